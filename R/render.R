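# Seeded RNG scope: run expr with a temporary seed, restoring the caller's
# RNG state afterwards so generators are reproducible without side effects.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Rendering configuration for synthetic OCT volumes
#'
#' Defaults emulate a spectral-domain OCT system with a field of view of
#' 1.7 x 1.7 x 2.2 mm and a depth pitch of 2 µm per pixel (optical path).
#'
#' @param zPitch depth pitch, optical micrometres per pixel.
#' @param lateralPitch lateral pitch, geometric micrometres per pixel.
#' @param dims integer(3) volume shape `[x, y, z]` in pixels.
#' @param interfaceBrightness peak intensity of interface bands (a.u., 16-bit
#'   scale).
#' @param shellBrightness peak intensity of the peripheral globe shell.
#' @param background mean background intensity.
#' @param speckleSd standard deviation of additive speckle-like noise.
#' @param zOffset optical depth of the anterior corneal surface (µm).
#' @param sigmaZ axial Gaussian half-width of an interface band (optical µm).
#' @param capRadius radius of curvature of the rendered interface caps (µm);
#'   anterior interfaces bow posteriorly off-axis and posterior interfaces
#'   anteriorly, which makes the central A-scan the one with the largest
#'   anterior-to-posterior extent. The curvature is cosmetic: all axial
#'   biometry is taken near the axis.
#' @param capExtent lateral radius (µm) over which interface caps are drawn;
#'   beyond it only the globe shell is rendered.
#' @param shellWidth relative width of the globe-shell band (dimensionless,
#'   in units of the normalized ellipsoid radius).
#' @return a list of class `OctRenderConfig`.
#' @export
octRenderConfig <- function(zPitch = 2, lateralPitch = 20,
                            dims = c(85L, 85L, 1100L),
                            interfaceBrightness = 20000,
                            shellBrightness = 15000,
                            background = 1000, speckleSd = 800,
                            zOffset = 60, sigmaZ = 2.5,
                            capRadius = 40000, capExtent = 400,
                            shellWidth = 0.08) {
  stopifnot(zPitch > 0, lateralPitch > 0, length(dims) == 3L, all(dims >= 3))
  structure(list(zPitch = zPitch, lateralPitch = lateralPitch,
                 dims = as.integer(dims),
                 interfaceBrightness = interfaceBrightness,
                 shellBrightness = shellBrightness, background = background,
                 speckleSd = speckleSd, zOffset = zOffset, sigmaZ = sigmaZ,
                 capRadius = capRadius, capExtent = capExtent,
                 shellWidth = shellWidth),
            class = "OctRenderConfig")
}

# Optical-path z positions (um) of the 7 interfaces for a geometry: the
# cumulative sum of geometric thickness x refractive index, anterior first.
opticalBoundaries <- function(geom, indices, zOffset = 0) {
  t <- geometryValues(geom)[.COMPONENT_NAMES_GEOM]
  n <- c(indices@cornea, indices@anteriorChamber, indices@lens,
         indices@vitreous, indices@retina, indices@rpe)
  z <- zOffset + c(0, cumsum(t * n))
  names(z) <- .BOUNDARY_NAMES
  z
}

#' Render a synthetic OCT volume from an eye geometry
#'
#' Forward model for the SD-OCT assay: the seven ocular interfaces are drawn
#' as bright bands whose central-axis depth equals the cumulative optical
#' path (geometric thickness times compartment refractive index), with
#' sub-pixel placement via Gaussian intensity deposition; the peripheral
#' globe is drawn as an ellipsoidal shell so that the equatorial extent is
#' visible on en-face slices; additive speckle-like noise completes the
#' volume. [segmentAxialBoundaries()] inverts this model.
#'
#' @param geom an [EyeGeometry-class].
#' @param cfg an [octRenderConfig()].
#' @param indices a [RefractiveIndexSet-class].
#' @param seed integer seed for the speckle noise; with `speckleSd = 0`
#'   renders are deterministic regardless of seed.
#' @return an [OctVolume-class].
#' @examples
#' cfg <- octRenderConfig(dims = c(31L, 31L, 920L), speckleSd = 0)
#' vol <- renderOctVolume(makeEyeGeometry("wt_6mpf"), cfg)
#' vol
#' @export
renderOctVolume <- function(geom, cfg = octRenderConfig(),
                            indices = refractiveIndices(), seed = NULL) {
  stopifnot(is(geom, "EyeGeometry"), is(indices, "RefractiveIndexSet"))
  dims <- cfg$dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  zb <- opticalBoundaries(geom, indices, cfg$zOffset)
  depth <- nz * cfg$zPitch
  if (zb[7] + 4 * cfg$sigmaZ >= depth)
    stop("geometry exceeds volume depth: posterior interface at ",
         round(zb[7], 1), " um (optical) but volume depth is ", depth, " um")

  vol <- array(cfg$background, dim = dims)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xum <- ((1:nx) - cx) * cfg$lateralPitch
  yum <- ((1:ny) - cy) * cfg$lateralPitch
  r2 <- outer(xum^2, yum^2, "+")

  # interface caps around the central axis; anterior interfaces (1-4) sag
  # posteriorly off-axis, posterior interfaces (5-7) sag anteriorly
  capIdx <- which(r2 <= cfg$capExtent^2)
  sag <- r2[capIdx] / (2 * cfg$capRadius)
  sagSign <- c(1, 1, 1, 1, -1, -1, -1)
  nxy <- nx * ny
  zvals <- ((1:nz) - 1) * cfg$zPitch
  win <- ceiling(4 * cfg$sigmaZ / cfg$zPitch)
  for (k in 1:7) {
    centers <- zb[k] + sagSign[k] * sag
    jmid <- round(zb[k] / cfg$zPitch) + 1
    for (j in max(1, jmid - win - 2):min(nz, jmid + win + 2)) {
      w <- exp(-((zvals[j] - centers)^2) / (2 * cfg$sigmaZ^2))
      vol[capIdx + (j - 1) * nxy] <- vol[capIdx + (j - 1) * nxy] +
        cfg$interfaceBrightness * w
    }
  }

  # peripheral globe shell (ellipsoid surface), outside the cap region
  ax <- geom@equatorialDiameterX / 2
  ay <- geom@equatorialDiameterY / 2
  az <- (zb[7] - zb[1]) / 2
  zmid <- (zb[1] + zb[7]) / 2
  A <- outer((xum / ax)^2, (yum / ay)^2, "+")
  ringIdx <- which(r2 > cfg$capExtent^2 & A <= (1 + 4 * cfg$shellWidth)^2)
  if (length(ringIdx)) {
    Ar <- A[ringIdx]
    for (j in 1:nz) {
      q <- Ar + ((zvals[j] - zmid) / az)^2
      keep <- abs(sqrt(q) - 1) < 4 * cfg$shellWidth
      if (any(keep)) {
        idx <- ringIdx[keep] + (j - 1) * nxy
        vol[idx] <- vol[idx] + cfg$shellBrightness *
          exp(-((sqrt(q[keep]) - 1)^2) / (2 * cfg$shellWidth^2))
      }
    }
  }

  if (cfg$speckleSd > 0) {
    vol <- withSeed(seed, vol + stats::rnorm(length(vol), 0, cfg$speckleSd))
  }
  vol[vol < 0] <- 0
  vol[vol > 65535] <- 65535
  new("OctVolume", data = vol, zPitch = cfg$zPitch,
      lateralPitch = cfg$lateralPitch)
}

#' Write / read an OCT volume as a multi-page TIFF with a JSON sidecar
#'
#' The z axis maps to TIFF pages; intensities are stored as 16-bit grayscale.
#' Pixel pitches travel in a JSON sidecar next to the TIFF
#' (`<file>.json`).
#'
#' @param volume an [OctVolume-class].
#' @param path output TIFF path.
#' @return `writeOctVolume` returns `path` invisibly; `readOctVolume`
#'   returns an [OctVolume-class].
#' @export
writeOctVolume <- function(volume, path) {
  stopifnot(is(volume, "OctVolume"))
  d <- dim(volume@data)
  pages <- lapply(seq_len(d[3]), function(j) volume@data[, , j] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(z_pitch_um = volume@zPitch, lateral_pitch_um = volume@lateralPitch,
         dims = d),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeOctVolume
#' @export
readOctVolume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(dim(pages[[1]]), length(pages))
  vol <- array(unlist(pages, use.names = FALSE), dim = d) * 65535
  new("OctVolume", data = vol, zPitch = meta$z_pitch_um,
      lateralPitch = meta$lateral_pitch_um)
}
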