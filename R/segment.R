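#' Segment the seven axial ocular interfaces of an OCT volume
#'
#' The central axis is located as the lateral A-scan position with the
#' largest anterior-to-posterior extent of supra-threshold signal. A median
#' intensity profile over a band of columns around the axis suppresses
#' speckle; the seven interfaces are then the ordered intensity peaks of that
#' profile, with three-point parabolic interpolation providing sub-pixel
#' axial positions (needed to resolve micrometre-scale corneal effects at a
#' 2 µm depth pitch).
#'
#' @param volume an [OctVolume-class].
#' @param band half-width (columns) of the averaging band around the axis.
#' @param nInterfaces number of interfaces expected (7 for a phakic eye).
#' @param peakFrac minimum peak height, as a fraction of the
#'   background-to-maximum intensity range, for a peak to count as an
#'   interface (prominence filter).
#' @return a [BoundarySet-class] with positions in optical-path micrometres.
#' @seealso [correctOpticalPath()], [computeBiometry()]
#' @export
segmentAxialBoundaries <- function(volume, band = 10L, nInterfaces = 7L,
                                   peakFrac = 0.25) {
  pk <- .findAxialPeaks(volume, band, nInterfaces, peakFrac)
  zpos <- pk$positions
  names(zpos) <- .BOUNDARY_NAMES
  if (any(diff(zpos) <= 0))
    stop("segmentation qc failure: interface ordering violated")
  new("BoundarySet", positions = zpos, axis = pk$axis,
      zPitch = volume@zPitch)
}

# Core peak finder shared by the 7-interface segmentation and the
# cornea-lens-contact fallback (6 resolvable interfaces).
.findAxialPeaks <- function(volume, band, nPeaks, peakFrac) {
  stopifnot(is(volume, "OctVolume"))
  vol <- volume@data
  d <- dim(vol)
  bg <- .bgEstimate(vol)
  mx <- max(vol)
  if (mx - bg <= 0 || (mx - bg) < 1e-6 * max(1, abs(mx)))
    stop("no interfaces found: volume has no contrast")
  thr <- bg + 0.3 * (mx - bg)

  nxy <- d[1] * d[2]
  idx <- which(vol > thr)
  col <- ((idx - 1L) %% nxy) + 1L
  z <- ((idx - 1L) %/% nxy) + 1L
  first <- integer(nxy); last <- integer(nxy)
  first[] <- NA_integer_; last[] <- NA_integer_
  ord <- order(z, decreasing = TRUE)
  first[col[ord]] <- z[ord]      # final write per column = minimal z
  ord <- order(z)
  last[col[ord]] <- z[ord]       # final write per column = maximal z
  extent <- ifelse(is.na(first), -1L, last - first)
  # centroid of the near-maximal plateau: with gently curved interfaces many
  # columns tie at the maximal pixel extent; their centroid is the axis
  sel <- which(extent >= max(extent) - 2L)
  axis <- round(colMeans(arrayInd(sel, d[1:2])))

  ix <- max(1L, axis[1] - band):min(d[1], axis[1] + band)
  iy <- max(1L, axis[2] - band):min(d[2], axis[2] + band)
  prof <- apply(vol[ix, iy, , drop = FALSE], 3, stats::median)

  pbg <- stats::median(prof)
  minh <- pbg + peakFrac * (max(prof) - pbg)
  pk <- pracma::findpeaks(prof, minpeakheight = minh, minpeakdistance = 3)
  if (is.null(pk) || nrow(pk) < nPeaks) {
    found <- if (is.null(pk)) 0L else nrow(pk)
    stop("segmentation qc failure: expected ", nPeaks,
         " interfaces but found ", found,
         " (missing ", nPeaks - found, ")")
  }
  if (nrow(pk) > nPeaks) {
    pk <- pk[order(pk[, 1], decreasing = TRUE)[1:nPeaks], , drop = FALSE]
  }
  pos <- sort(pk[, 2])

  # parabolic 3-point sub-pixel refinement
  sub <- vapply(pos, function(p) {
    if (p <= 1 || p >= length(prof)) return(as.numeric(p))
    y0 <- prof[p - 1]; y1 <- prof[p]; y2 <- prof[p + 1]
    den <- y0 - 2 * y1 + y2
    delta <- if (abs(den) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / den
    p + max(-0.5, min(0.5, delta))
  }, numeric(1))

  list(positions = (sub - 1) * volume@zPitch, axis = as.integer(axis))
}

#' Convert optical-path interface positions to geometric thicknesses
#'
#' SD-OCT depth is optical path length, so each compartment's geometric
#' thickness is its optical extent divided by the compartment refractive
#' index: cornea 1.33, anterior chamber 1.34, lens 1.40, vitreous chamber
#' 1.34, retina 1.38 and RPE (retinal index) by default.
#'
#' @param boundaries a [BoundarySet-class].
#' @param indices a [RefractiveIndexSet-class].
#' @return named numeric(6) of geometric thicknesses (µm): corneal
#'   thickness, ACD, lens diameter, VCD, retinal thickness, RPE thickness.
#' @examples
#' # a lens spanning 140 um of optical path is 100 um thick at n = 1.40
#' 140 / 1.40
#' @export
correctOpticalPath <- function(boundaries, indices = refractiveIndices()) {
  stopifnot(is(boundaries, "BoundarySet"), is(indices, "RefractiveIndexSet"))
  dz <- diff(boundaries@positions)
  if (any(dz <= 0)) stop("interface positions must strictly increase")
  n <- c(indices@cornea, indices@anteriorChamber, indices@lens,
         indices@vitreous, indices@retina, indices@rpe)
  out <- as.numeric(dz) / n
  names(out) <- .COMPONENT_NAMES
  out
}

# Background intensity estimate: median over a strided subsample (volumes
# are large and mostly background; an exact full-volume median is wasteful).
.bgEstimate <- function(vol) {
  stats::median(vol[seq(1L, length(vol), by = max(1L, length(vol) %/% 2e5))])
}

# Equatorial diameter (um) along one lateral axis of the mid-depth en-face
# slice: distance between the outermost intensity peaks of the profile
# through the volume centre, with parabolic sub-pixel refinement.
.enfaceDiameter <- function(slice, pitch, centerIdx, bg) {
  prof <- rowMeans(slice[, pmax(1, centerIdx - 1):pmin(ncol(slice),
                                                       centerIdx + 1),
                         drop = FALSE])
  minh <- bg + 0.4 * (max(prof) - bg)
  pk <- pracma::findpeaks(prof, minpeakheight = minh, minpeakdistance = 2)
  if (is.null(pk) || nrow(pk) < 2) return(NA_real_)
  lo <- pk[which.min(pk[, 2]), 2]
  hi <- pk[which.max(pk[, 2]), 2]
  ref <- function(p) {
    if (p <= 1 || p >= length(prof)) return(as.numeric(p))
    den <- prof[p - 1] - 2 * prof[p] + prof[p + 1]
    d <- if (abs(den) < .Machine$double.eps) 0 else
      0.5 * (prof[p - 1] - prof[p + 1]) / den
    p + max(-0.5, min(0.5, d))
  }
  (ref(hi) - ref(lo)) * pitch
}

#' Compute per-eye biometric endpoints from an OCT volume
#'
#' Segments the seven axial interfaces, converts optical to geometric
#' distances with the per-compartment refractive indices, and derives the
#' eight endpoints: the six compartment thicknesses, the axial length (their
#' sum; the RPE is included in the axial length) and an ellipsoid eye-volume
#' estimate `(4/3) * pi * a * b * c` from the axial semi-axis and the two
#' equatorial semi-axes measured on the mid-depth en-face slice.
#'
#' @param volume an [OctVolume-class].
#' @param indices a [RefractiveIndexSet-class].
#' @param band,peakFrac passed to [segmentAxialBoundaries()].
#' @return a [BiometryRecord-class]. QC flags: `acd_at_floor` when the
#'   anterior chamber depth is below 2 µm (a near-zero anterior chamber
#'   merges the cornea-inner and lens-anterior reflections; the six-peak
#'   case is interpreted as cornea-lens contact and reported as ACD 0),
#'   `no_equatorial_signal` when the en-face extent is not measurable (eye
#'   volume is then `NA`).
#' @export
computeBiometry <- function(volume, indices = refractiveIndices(),
                            band = 10L, peakFrac = 0.25) {
  qc <- character(0)
  bset <- tryCatch(
    segmentAxialBoundaries(volume, band = band, peakFrac = peakFrac),
    error = function(e) e)
  if (inherits(bset, "error")) {
    # an anterior chamber near zero merges the cornea-inner and
    # lens-anterior reflections into one peak; treat the 6-peak case as
    # cornea-lens contact (ACD 0) rather than failing
    pk <- tryCatch(.findAxialPeaks(volume, band, 6L, peakFrac),
                   error = function(e) NULL)
    if (is.null(pk)) stop(bset)
    zpos <- c(pk$positions[1:2], pk$positions[2] + 1e-6, pk$positions[3:6])
    names(zpos) <- .BOUNDARY_NAMES
    bset <- new("BoundarySet", positions = zpos, axis = pk$axis,
                zPitch = volume@zPitch)
  }
  comp <- correctOpticalPath(bset, indices)
  if (comp[["acd"]] < 2) qc <- c(qc, "acd_at_floor")

  vol <- volume@data
  d <- dim(vol)
  zmid <- (bset@positions[1] + bset@positions[7]) / 2
  jmid <- max(1L, min(d[3], round(zmid / volume@zPitch) + 1L))
  slice <- vol[, , jmid]
  bg <- .bgEstimate(vol)
  dx <- .enfaceDiameter(slice, volume@lateralPitch, bset@axis[2], bg)
  dy <- .enfaceDiameter(t(slice), volume@lateralPitch, bset@axis[1], bg)
  axial <- sum(comp)
  eyeVol <- if (is.na(dx) || is.na(dy)) {
    qc <- c(qc, "no_equatorial_signal")
    NA_real_
  } else {
    (pi / 6) * dx * dy * axial
  }

  new("BiometryRecord",
      cornealThickness = unname(comp[["corneal_thickness"]]),
      acd = unname(comp[["acd"]]),
      lensDiameter = unname(comp[["lens_diameter"]]),
      vcd = unname(comp[["vcd"]]),
      retinalThickness = unname(comp[["retinal_thickness"]]),
      rpeThickness = unname(comp[["rpe_thickness"]]),
      axialLength = unname(axial), eyeVolume = eyeVol, qcFlags = qc)
}
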