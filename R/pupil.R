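#' Render a synthetic infrared pupil frame
#'
#' Forward model for eccentric photorefraction: under eccentric infrared
#' illumination the pupil shows a vertical brightness gradient whose slope is
#' (after lens calibration) proportional to the refractive error. The frame
#' is a bright disk with a linear vertical intensity ramp on a darker
#' background, 8-bit grayscale.
#'
#' @param slope brightness slope in intensity a.u. per pupil radius; positive
#'   slope makes the bottom of the pupil brighter, negative the top.
#' @param center numeric(2) pupil centre as `(row, col)` pixels.
#' @param radius pupil radius in pixels (>= 5).
#' @param noiseSd additive Gaussian intensity noise (a.u.).
#' @param seed integer seed for the noise.
#' @param size frame size `(rows, cols)`.
#' @param baseIntensity mean pupil intensity (a.u., 0-255).
#' @param background background intensity.
#' @return integer matrix (rows x cols) with values in 0-255.
#' @export
renderPupilFrame <- function(slope, center = c(48, 48), radius = 30,
                             noiseSd = 0, seed = NULL, size = c(96, 96),
                             baseIntensity = 150, background = 40) {
  if (radius < 5) stop("pupil radius must be >= 5 px")
  if (center[1] - radius < 1 || center[1] + radius > size[1] ||
      center[2] - radius < 1 || center[2] + radius > size[2])
    stop("pupil does not fit inside the frame")
  rr <- outer((1:size[1]) - center[1], (1:size[2]) - center[2],
              function(a, b) sqrt(a^2 + b^2))
  w <- pmin(1, pmax(0, radius + 0.5 - rr))
  ramp <- baseIntensity + slope * (((1:size[1]) - center[1]) / radius)
  img <- background + w * (matrix(ramp, size[1], size[2]) - background)
  if (noiseSd > 0)
    img <- withSeed(seed, img + stats::rnorm(length(img), 0, noiseSd))
  img[img < 0] <- 0
  img[img > 255] <- 255
  round(img)
}

#' Detect the pupil in an infrared frame
#'
#' Thresholds the frame at the mid-intensity, labels connected components
#' and keeps near-circular candidates (circularity `4*pi*A/P^2` at least
#' `minCircularity`); the largest candidate wins.
#'
#' @param image numeric matrix, 8- or 16-bit grayscale.
#' @param threshold intensity threshold; default midway between the minimum
#'   and maximum of the frame.
#' @param minCircularity minimum circularity of a candidate region.
#' @return list with `center` (`(row, col)`, pixels) and `radius` (pixels,
#'   from the region area).
#' @export
detectPupil <- function(image, threshold = NULL, minCircularity = 0.8) {
  stopifnot(is.matrix(image))
  if (is.null(threshold)) threshold <- (min(image) + max(image)) / 2
  mask <- image > threshold
  if (!any(mask)) stop("no pupil candidate region found")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  sh <- EBImage::computeFeatures.shape(lab)
  mo <- EBImage::computeFeatures.moment(lab)
  if (is.null(sh) || nrow(sh) == 0) stop("no pupil candidate region found")
  circ <- pmin(1, 4 * pi * sh[, "s.area"] / pmax(sh[, "s.perimeter"], 1)^2)
  ok <- which(circ >= minCircularity & sh[, "s.area"] >= pi * 25)
  if (!length(ok)) stop("no sufficiently circular pupil candidate found")
  best <- ok[which.max(sh[ok, "s.area"])]
  list(center = c(mo[best, "m.cx"], mo[best, "m.cy"]),
       radius = sqrt(sh[best, "s.area"] / pi))
}

#' Brightness-gradient slope across the pupil
#'
#' Least-squares linear fit of intensity against vertical position
#' (normalized to the pupil radius) along the central vertical chord of the
#' pupil, excluding a 10% rim to avoid edge roll-off.
#'
#' @param image numeric matrix.
#' @param pupil list with `center` and `radius`, as from [detectPupil()].
#' @param rimFraction fraction of the radius excluded at the rim.
#' @param chordHalfWidth half-width (columns) of the chord averaged over.
#' @param saturationLevel intensity treated as sensor saturation.
#' @return list with `slope` (a.u. per pupil radius), `intercept`, `r2`,
#'   and `qcFlags` (contains `"saturated_pupil"` when more than 20% of chord
#'   pixels sit at the saturation level).
#' @export
brightnessSlope <- function(image, pupil, rimFraction = 0.1,
                            chordHalfWidth = 1, saturationLevel = 255) {
  r <- pupil$radius
  if (r < 5) stop("pupil radius must be >= 5 px")
  cr <- pupil$center[1]; cc <- pupil$center[2]
  span <- (1 - rimFraction) * r
  rows <- max(1, ceiling(cr - span)):min(nrow(image), floor(cr + span))
  cols <- max(1, round(cc - chordHalfWidth)):min(ncol(image),
                                                 round(cc + chordHalfWidth))
  vals <- rowMeans(image[rows, cols, drop = FALSE])
  x <- (rows - cr) / r
  qc <- character(0)
  if (mean(image[rows, cols] >= saturationLevel) > 0.2)
    qc <- c(qc, "saturated_pupil")
  fit <- stats::lm.fit(cbind(1, x), vals)
  res <- vals - cbind(1, x) %*% fit$coefficients
  tss <- sum((vals - mean(vals))^2)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r2 = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
       qcFlags = qc)
}

#' Fit a slope-to-diopter calibration from ophthalmic lens measurements
#'
#' @param points data.frame with columns `slope` (a.u. per pupil radius) and
#'   `diopters` (known lens power, D); at least two distinct slopes.
#' @return a [RefractionCalibration-class] with the OLS fit
#'   `diopters = gain * slope + offset`.
#' @export
calibrateRefraction <- function(points) {
  stopifnot(is.data.frame(points), all(c("slope", "diopters") %in%
                                         names(points)))
  if (nrow(points) < 2 || length(unique(points$slope)) < 2)
    stop("calibration requires >= 2 distinct slope values")
  fit <- stats::lm(diopters ~ slope, data = points)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 1
  new("RefractionCalibration", gain = unname(stats::coef(fit)[2]),
      offset = unname(stats::coef(fit)[1]), fitR2 = min(1, max(0, r2)),
      lensPoints = points[, c("slope", "diopters")])
}

#' Default photorefraction calibration
#'
#' The calibration of the physical instrument is device-specific; this
#' default is the calibration of the package's own forward model
#' ([renderPupilFrame()]), under which synthetic cohorts are generated and
#' analyzed. Analyses of genotype differences are invariant to the gain used,
#' as long as generation and analysis share it.
#'
#' @param gain diopters per (a.u./pupil radius).
#' @param offset diopters.
#' @return a [RefractionCalibration-class].
#' @export
defaultCalibration <- function(gain = 0.5, offset = 0) {
  s <- c(-20, 0, 20, 40)
  calibrateRefraction(data.frame(slope = s, diopters = gain * s + offset))
}

#' Average the refractive error over a set of pupil frames
#'
#' Each frame contributes one brightness-slope measurement, converted to
#' diopters through the calibration; the per-eye result is the mean over
#' frames (the protocol takes 100 independent measurements per eye and
#' averages them).
#'
#' @param frames list of grayscale matrices.
#' @param calibration a [RefractionCalibration-class].
#' @param ... passed to [detectPupil()].
#' @return a [RefractionResult-class]. Frames in which no pupil is found are
#'   dropped with a `dropped_frames:<k>` qc flag; a single usable frame
#'   yields `sdDiopters = 0` with a `single_frame` flag.
#' @export
measureRefraction <- function(frames, calibration = defaultCalibration(),
                              ...) {
  stopifnot(length(frames) >= 1, is(calibration, "RefractionCalibration"))
  qc <- character(0)
  slopes <- numeric(0)
  nFail <- 0L
  for (f in frames) {
    res <- tryCatch({
      p <- detectPupil(f, ...)
      brightnessSlope(f, p)
    }, error = function(e) NULL)
    if (is.null(res)) {
      nFail <- nFail + 1L
    } else {
      slopes <- c(slopes, res$slope)
      qc <- union(qc, res$qcFlags)
    }
  }
  if (!length(slopes))
    stop("pupil detection failed in all ", length(frames), " frames")
  if (nFail > 0) qc <- c(qc, paste0("dropped_frames:", nFail))
  d <- calibration@gain * slopes + calibration@offset
  sdD <- if (length(d) > 1) stats::sd(d) else {
    qc <- c(qc, "single_frame"); 0
  }
  new("RefractionResult", meanDiopters = mean(d), sdDiopters = sdD,
      nMeasurements = length(d), slopes = slopes, qcFlags = qc)
}
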