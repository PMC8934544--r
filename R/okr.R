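#' Construct a binocular eye-angle trace
#'
#' @param time seconds, uniformly sampled.
#' @param angleLeft,angleRight eye angles, degrees.
#' @param sampleRate Hz.
#' @param stimulus list with `drum_velocity` (deg/s), `spatial_frequency`
#'   (cycles/deg) and `direction` (`"cw"` or `"ccw"`).
#' @return an [AngleTrace-class].
#' @export
angleTrace <- function(time, angleLeft, angleRight, sampleRate,
                       stimulus = list(drum_velocity = 20,
                                       spatial_frequency = 0.15,
                                       direction = "cw")) {
  new("AngleTrace", time = time, angleLeft = angleLeft,
      angleRight = angleRight, sampleRate = sampleRate, stimulus = stimulus)
}

#' Synthesize an optokinetic nystagmus trace
#'
#' Forward model for the OKR assay: the eye tracks the rotating drum
#' linearly at the slow-phase velocity and is reset by an instantaneous
#' saccade of the given amplitude, in the direction opposite the drift,
#' every `saccadeInterval` seconds (a sawtooth). Both eyes receive the same
#' sawtooth plus independent angle noise. A zero slow-phase velocity yields
#' a flat trace with no saccades (the non-responder phenotype).
#'
#' @param slowPhaseVelocity slow-phase eye velocity, deg/s (sign follows the
#'   stimulus direction; pass the magnitude for a `"cw"` drum).
#' @param saccadeInterval seconds between resetting saccades
#'   (> `2/sampleRate`).
#' @param saccadeAmplitude saccade amplitude, degrees.
#' @param duration trace duration, seconds (>= 30).
#' @param sampleRate Hz (>= 25).
#' @param noiseSd additive angle noise, degrees.
#' @param seed integer seed.
#' @param drumVelocity,spatialFrequency,direction stimulus metadata.
#' @return an [AngleTrace-class].
#' @export
synthOkrTrace <- function(slowPhaseVelocity, saccadeInterval = 1,
                          saccadeAmplitude = slowPhaseVelocity *
                            saccadeInterval,
                          duration = 60, sampleRate = 60, noiseSd = 0,
                          seed = NULL, drumVelocity = 20,
                          spatialFrequency = 0.15, direction = "cw") {
  if (sampleRate < 25) stop("sampleRate must be >= 25 Hz")
  if (duration < 30) stop("duration must be >= 30 s")
  if (saccadeInterval <= 2 / sampleRate)
    stop("saccadeInterval must exceed 2/sampleRate")
  n <- round(duration * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  s <- if (direction == "ccw") -1 else 1
  base <- if (slowPhaseVelocity == 0) {
    rep(0, n)
  } else {
    s * (slowPhaseVelocity * t -
           saccadeAmplitude * floor(t / saccadeInterval))
  }
  withSeed(seed, {
    left <- base + if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
    right <- base + if (noiseSd > 0) stats::rnorm(n, 0, noiseSd) else 0
    angleTrace(t, left, right, sampleRate,
               list(drum_velocity = drumVelocity,
                    spatial_frequency = spatialFrequency,
                    direction = direction))
  })
}

.eyeAngle <- function(trace, eye) {
  switch(match.arg(eye, c("left", "right")),
         left = trace@angleLeft, right = trace@angleRight)
}

# Smoothed angular velocity (deg/s) via a Savitzky-Golay first-derivative
# filter over `window` seconds.
.smoothedVelocity <- function(angle, sampleRate, window = 0.2) {
  nw <- max(5L, round(window * sampleRate))
  if (nw %% 2 == 0) nw <- nw + 1L
  nw <- min(nw, if (length(angle) %% 2 == 0) length(angle) - 1L
            else length(angle))
  signal::sgolayfilt(angle, p = 2, n = nw, m = 1) * sampleRate
}

#' Detect resetting saccades in an eye-angle trace
#'
#' A saccade is a sample where the smoothed angular velocity
#' (Savitzky-Golay derivative, 0.2 s window) exceeds the threshold with sign
#' opposite to the stimulus-driven slow phase; consecutive supra-threshold
#' samples form one event (time of peak speed), and events closer than
#' `mergeGap` are merged.
#'
#' @param trace an [AngleTrace-class].
#' @param velocityThreshold deg/s; the default 100 deg/s cleanly separates
#'   saccades from a 20 deg/s slow phase.
#' @param smoothWindow smoothing window, seconds.
#' @param mergeGap minimum separation between events, seconds.
#' @param eye `"left"` or `"right"`.
#' @return numeric vector of saccade times (seconds), possibly empty.
#' @export
detectSaccades <- function(trace, velocityThreshold = 100,
                           smoothWindow = 0.2, mergeGap = 0.1,
                           eye = "left") {
  stopifnot(is(trace, "AngleTrace"), length(trace@time) >= 2)
  angle <- .eyeAngle(trace, eye)
  vel <- .smoothedVelocity(angle, trace@sampleRate, smoothWindow)
  s <- if (identical(trace@stimulus$direction, "ccw")) -1 else 1
  cand <- which(-s * vel > velocityThreshold)
  if (!length(cand)) return(numeric(0))
  gap <- max(1L, round(mergeGap * trace@sampleRate))
  breaks <- c(0, which(diff(cand) > gap), length(cand))
  times <- numeric(length(breaks) - 1)
  for (i in seq_along(times)) {
    run <- cand[(breaks[i] + 1):breaks[i + 1]]
    times[i] <- trace@time[run[which.max(abs(vel[run]))]]
  }
  times
}

#' Segment slow phases and estimate the slow-phase eye velocity
#'
#' Slow phases are the intervals between consecutive saccades (trimmed by a
#' guard interval around each saccade). Each segment of at least
#' `minDuration` gets a least-squares slope; segments with
#' r-squared below `r2Min` are discarded. The per-eye velocity is the median
#' of the retained segment slopes and the per-fish velocity averages the
#' two eyes (temporally and nasally directed movements are averaged per
#' fish).
#'
#' @param trace an [AngleTrace-class].
#' @param saccades optional list with elements `left` and `right` of saccade
#'   times; computed by [detectSaccades()] when missing.
#' @param minDuration minimum usable segment length, seconds.
#' @param guard trim around each saccade, seconds.
#' @param r2Min minimum r-squared of a slow-phase linear fit; a fish whose
#'   segments all fall below this is a non-responder.
#' @param ... passed to [detectSaccades()].
#' @return list with `velocity` (per-fish mean absolute slow-phase velocity,
#'   deg/s; `NA` for non-responders), `perEye` (named numeric), `segments`
#'   (data.frame: eye, start, end, slope, r2, used), and `noResponse`.
#' @export
slowPhaseVelocity <- function(trace, saccades = NULL, minDuration = 0.3,
                              guard = 0.05, r2Min = 0.8, ...) {
  stopifnot(is(trace, "AngleTrace"))
  if (is.null(saccades))
    saccades <- list(left = detectSaccades(trace, eye = "left", ...),
                     right = detectSaccades(trace, eye = "right", ...))
  segs <- list()
  perEye <- c(left = NA_real_, right = NA_real_)
  for (eye in c("left", "right")) {
    angle <- .eyeAngle(trace, eye)
    bounds <- c(min(trace@time), sort(saccades[[eye]]), max(trace@time))
    slopes <- numeric(0)
    for (i in seq_len(length(bounds) - 1)) {
      t0 <- bounds[i] + guard
      t1 <- bounds[i + 1] - guard
      if (t1 - t0 < minDuration) next
      sel <- trace@time >= t0 & trace@time <= t1
      if (sum(sel) < 3) next
      x <- trace@time[sel]; y <- angle[sel]
      fit <- stats::lm.fit(cbind(1, x), y)
      res <- y - cbind(1, x) %*% fit$coefficients
      tss <- sum((y - mean(y))^2)
      r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
      used <- is.finite(r2) && r2 >= r2Min
      segs[[length(segs) + 1]] <- data.frame(
        eye = eye, start = t0, end = t1,
        slope = unname(fit$coefficients[2]), r2 = r2, used = used)
      if (used) slopes <- c(slopes, fit$coefficients[2])
    }
    if (length(slopes)) perEye[eye] <- stats::median(slopes)
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(eye = character(), start = numeric(), end = numeric(),
               slope = numeric(), r2 = numeric(), used = logical())
  noResponse <- all(is.na(perEye))
  list(velocity = if (noResponse) NA_real_ else
         mean(abs(perEye), na.rm = TRUE),
       perEye = perEye, segments = segments, noResponse = noResponse)
}

#' Optokinetic gain
#'
#' Ratio between the slow-phase eye-tracking velocity and the stimulus
#' (drum) velocity.
#'
#' @param eyeVelocity slow-phase eye velocity, deg/s.
#' @param drumVelocity drum velocity, deg/s (non-zero).
#' @return dimensionless gain, `|eyeVelocity| / |drumVelocity|`.
#' @examples
#' optokineticGain(20, 20)  # 1
#' optokineticGain(10, 20)  # 0.5
#' @export
optokineticGain <- function(eyeVelocity, drumVelocity) {
  if (any(drumVelocity == 0)) stop("drum velocity must be non-zero")
  abs(eyeVelocity) / abs(drumVelocity)
}

#' Count eye-tracking movements per interval
#'
#' An eye-tracking movement (ETM) is one slow-phase/saccade cycle; counts
#' are reported per consecutive window (15 s by default) during the
#' unidirectional stimulation, dropping a partial trailing window.
#'
#' @param trace an [AngleTrace-class].
#' @param saccades saccade times (seconds); computed from the left eye by
#'   [detectSaccades()] when missing (during unidirectional stimulation
#'   both eyes move together and have equal counts).
#' @param window interval length, seconds.
#' @param ... passed to [detectSaccades()].
#' @return integer vector of counts, one per complete window.
#' @export
countEtms <- function(trace, saccades = NULL, window = 15, ...) {
  stopifnot(is(trace, "AngleTrace"))
  duration <- max(trace@time) - min(trace@time) + 1 / trace@sampleRate
  # epsilon guards the bin count against float error in reconstructed times
  nBins <- floor(duration / window + 1e-9)
  if (nBins < 1) stop("trace duration is shorter than the counting window")
  if (is.null(saccades)) saccades <- detectSaccades(trace, eye = "left", ...)
  t0 <- min(trace@time)
  vapply(seq_len(nBins), function(b) {
    sum(saccades >= t0 + (b - 1) * window & saccades < t0 + b * window)
  }, integer(1))
}

#' Full optokinetic analysis of one fish
#'
#' Combines saccade detection, slow-phase segmentation, per-direction gain
#' and ETM counting. Direction labels follow the dorsal-view convention for
#' a clockwise drum: the left eye performs temporal-to-nasal tracking and
#' the right eye nasal-to-temporal (swapped for a counter-clockwise drum).
#'
#' @param trace an [AngleTrace-class].
#' @param etmWindow ETM counting window, seconds.
#' @param ... passed to [slowPhaseVelocity()].
#' @return an [OkrResult-class]. Non-responders (no slow-phase segment with
#'   acceptable linearity in either eye) carry `noResponse = TRUE`,
#'   undefined gains and zero ETM counts.
#' @export
analyzeOkr <- function(trace, etmWindow = 15, ...) {
  spv <- slowPhaseVelocity(trace, ...)
  drum <- trace@stimulus$drum_velocity
  cw <- !identical(trace@stimulus$direction, "ccw")
  tnEye <- if (cw) "left" else "right"
  ntEye <- if (cw) "right" else "left"
  if (spv$noResponse) {
    nBins <- max(1, floor((max(trace@time) - min(trace@time) +
                             1 / trace@sampleRate) / etmWindow + 1e-9))
    return(new("OkrResult", gainTn = NA_real_, gainNt = NA_real_,
               etmPer15s = integer(nBins), nSegments = 0L,
               noResponse = TRUE))
  }
  gTn <- if (is.na(spv$perEye[tnEye])) NA_real_ else
    optokineticGain(spv$perEye[tnEye], drum)
  gNt <- if (is.na(spv$perEye[ntEye])) NA_real_ else
    optokineticGain(spv$perEye[ntEye], drum)
  etm <- countEtms(trace, window = etmWindow)
  new("OkrResult", gainTn = unname(gTn), gainNt = unname(gNt),
      etmPer15s = etm, nSegments = sum(spv$segments$used),
      noResponse = FALSE)
}

#' Render dorsal-view frames of the two eyes at known angles
#'
#' Forward model for the eye tracker: each frame shows two dark ellipses
#' (the eyes, dorsal view) on a lighter body/background, both rotated to the
#' given angle. Used to validate [trackEyeAngles()] against ground truth.
#'
#' @param theta numeric vector of eye angles per frame, degrees.
#' @param size frame size `(rows, cols)`.
#' @param eyeCenters 2x2 matrix of `(row, col)` centres, one row per eye.
#' @param semiAxes ellipse semi-axes `(major, minor)` in pixels.
#' @param background,eyeIntensity gray levels (0-255).
#' @return list of matrices, one per frame.
#' @export
renderEyeFrames <- function(theta, size = c(64, 96),
                            eyeCenters = rbind(c(32, 30), c(32, 66)),
                            semiAxes = c(12, 6), background = 200,
                            eyeIntensity = 30) {
  a <- semiAxes[1]; b <- semiAxes[2]
  rows <- matrix(1:size[1], size[1], size[2])
  cols <- matrix(1:size[2], size[1], size[2], byrow = TRUE)
  lapply(theta, function(th) {
    rad <- th * pi / 180
    img <- matrix(background, size[1], size[2])
    for (e in 1:2) {
      dx <- rows - eyeCenters[e, 1]
      dy <- cols - eyeCenters[e, 2]
      u <- cos(rad) * dx + sin(rad) * dy
      v <- -sin(rad) * dx + cos(rad) * dy
      q <- sqrt((u / a)^2 + (v / b)^2)
      w <- pmin(1, pmax(0, (1 + 0.5 / b) - q) * (2 * b))
      img <- img - w * (background - eyeIntensity)
    }
    pmax(img, eyeIntensity)
  })
}

#' Track eye angles in dorsal-view frames
#'
#' Per frame: threshold at mid-intensity, label connected dark components,
#' keep the two largest (the eyes), and take each eye's orientation from
#' second-order image moments. Eyes are assigned left/right by lateral
#' position; angles are unwrapped over time (orientation is defined modulo
#' 180 degrees). Frames in which fewer than two components are found are
#' interpolated, but if they exceed `maxFailFraction` the trace is rejected.
#'
#' @param frames list of grayscale matrices.
#' @param sampleRate Hz.
#' @param stimulus stimulus metadata list (see [angleTrace()]).
#' @param threshold intensity threshold; default midway min/max of frame 1.
#' @param maxFailFraction maximum tolerated fraction of failed frames.
#' @return an [AngleTrace-class].
#' @export
trackEyeAngles <- function(frames, sampleRate = 60,
                           stimulus = list(drum_velocity = 20,
                                           spatial_frequency = 0.15,
                                           direction = "cw"),
                           threshold = NULL, maxFailFraction = 0.1) {
  stopifnot(length(frames) >= 2)
  if (is.null(threshold))
    threshold <- (min(frames[[1]]) + max(frames[[1]])) / 2
  n <- length(frames)
  angL <- rep(NA_real_, n); angR <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    mask <- frames[[i]] < threshold
    if (!any(mask)) next
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sh <- EBImage::computeFeatures.shape(lab)
    if (is.null(sh) || nrow(sh) < 2) next
    mo <- EBImage::computeFeatures.moment(lab)
    top2 <- order(sh[, "s.area"], decreasing = TRUE)[1:2]
    lr <- top2[order(mo[top2, "m.cy"])]   # smaller column = left eye
    angL[i] <- mo[lr[1], "m.theta"] * 180 / pi
    angR[i] <- mo[lr[2], "m.theta"] * 180 / pi
  }
  nFail <- sum(is.na(angL) | is.na(angR))
  if (nFail > maxFailFraction * n)
    stop("two eyes not found in ", nFail, "/", n, " frames")
  unwrap <- function(a) {
    ok <- which(!is.na(a))
    for (i in ok[-1]) {
      prev <- a[max(ok[ok < i])]
      k <- round((a[i] - prev) / 180)
      a[i] <- a[i] - 180 * k
    }
    if (anyNA(a)) {
      t <- seq_along(a)
      a <- stats::approx(t[!is.na(a)], a[!is.na(a)], t, rule = 2)$y
    }
    a
  }
  angleTrace((seq_len(n) - 1) / sampleRate, unwrap(angL), unwrap(angR),
             sampleRate, stimulus)
}
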