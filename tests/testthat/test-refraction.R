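test_that("pupil detection localizes the disk and rejects degenerate frames", {
  f <- renderPupilFrame(0, center = c(64, 64), radius = 20, size = c(128, 128))
  p <- detectPupil(f)
  expect_lt(max(abs(p$center - c(64, 64))), 1)
  expect_lt(abs(p$radius - 20), 1)

  expect_error(detectPupil(matrix(40, 64, 64)), "pupil")

  # two disks: the larger one wins
  f2 <- matrix(40, 128, 128)
  rr <- function(c1, c2, r) outer((1:128) - c1, (1:128) - c2,
                                  function(a, b) sqrt(a^2 + b^2)) <= r
  f2[rr(40, 40, 12)] <- 150
  f2[rr(90, 90, 22)] <- 150
  p2 <- detectPupil(f2)
  expect_lt(max(abs(p2$center - c(90, 90))), 1.5)
  expect_lt(abs(p2$radius - 22), 1.5)
})

test_that("brightness slope recovers the rendered ramp", {
  f0 <- renderPupilFrame(0, noiseSd = 0)
  p <- detectPupil(f0)
  expect_lt(abs(brightnessSlope(f0, p)$slope), 0.02)

  fs <- renderPupilFrame(30, noiseSd = 0)
  s <- brightnessSlope(fs, detectPupil(fs))$slope
  expect_lt(abs(s - 30) / 30, 0.01)

  # linearity of the least-squares slope, same pupil region for both
  pupil <- list(center = c(48, 48), radius = 30)
  sA <- brightnessSlope(renderPupilFrame(15, noiseSd = 0), pupil)$slope
  sB <- brightnessSlope(renderPupilFrame(30, noiseSd = 0), pupil)$slope
  expect_lt(abs(sB / sA - 2), 0.01)
})

test_that("lens calibration is an exact OLS fit with validity checks", {
  cal <- calibrateRefraction(data.frame(slope = c(0, 1), diopters = c(0, 10)))
  expect_equal(cal@gain, 10)
  expect_equal(cal@offset, 0)
  expect_equal(cal@fitR2, 1)

  exact <- data.frame(slope = c(-2, 0, 1, 3), diopters = 4 - 2.5 * c(-2, 0, 1, 3))
  expect_equal(calibrateRefraction(exact)@fitR2, 1)
  expect_equal(calibrateRefraction(exact)@gain, -2.5)

  expect_error(calibrateRefraction(data.frame(slope = c(1, 1),
                                              diopters = c(0, 5))),
               "distinct")

  # noisy 5-lens set: gain recovered within 5%
  set.seed(8)
  sl <- c(-20, -10, 0, 10, 20)
  noisy <- data.frame(slope = sl, diopters = 0.5 * sl + rnorm(5, 0, 0.3))
  expect_lt(abs(calibrateRefraction(noisy)@gain - 0.5) / 0.5, 0.05)
})

test_that("per-eye refraction averages calibrated frame slopes", {
  cal <- defaultCalibration()
  mk <- function(D, n, noiseSd = 0, seedBase = 0)
    lapply(seq_len(n), function(i)
      renderPupilFrame((D - cal@offset) / cal@gain, noiseSd = noiseSd,
                       seed = seedBase + i))

  res <- measureRefraction(mk(15, 10), cal)
  expect_lt(abs(res@meanDiopters - 15) / 15, 0.01)
  expect_equal(res@nMeasurements, 10L)

  # affine equivariance: shifting every slope by delta shifts diopters by
  # gain * delta
  res2 <- measureRefraction(mk(15 + cal@gain * 10, 10), cal)
  # tolerance reflects 8-bit frame quantization and pupil re-detection
  expect_lt(abs((res2@meanDiopters - res@meanDiopters) - cal@gain * 10), 0.5)

  one <- measureRefraction(mk(15, 1), cal)
  expect_equal(one@sdDiopters, 0)
  expect_true("single_frame" %in% one@qcFlags)

  blank <- list(matrix(40, 96, 96))
  expect_error(measureRefraction(blank, cal), "all")
  mixed <- c(mk(15, 5), blank)
  resMix <- measureRefraction(mixed, cal)
  expect_equal(resMix@nMeasurements, 5L)
  expect_true(any(grepl("dropped_frames:1", resMix@qcFlags)))
})

test_that("focal-length model and relative refractive error behave as defined", {
  expect_equal(idealizedFocalLength(100), 229.899)
  expect_equal(idealizedFocalLength(0), 11.699)
  expect_equal(idealizedFocalLength(101) - idealizedFocalLength(100), 2.182)

  f <- idealizedFocalLength(250)
  expect_equal(relativeRefractiveError(250, f), 0)
  expect_equal(relativeRefractiveError(250, 2 * f), -1)

  # monotone: hyperopic shift as the retina moves closer, myopic as the
  # lens grows
  rr <- relativeRefractiveError(250, seq(400, 700, by = 50))
  expect_true(all(diff(rr) < 0))
  rl <- relativeRefractiveError(seq(200, 300, by = 20), 550)
  expect_true(all(diff(rl) > 0))

  expect_error(relativeRefractiveError(250, 500, slopeCoeff = -1,
                                       intercept = 0), "positive")
})

test_that("shorter vitreous chambers shift the relative refractive error up", {
  gW <- geometryValues(makeEyeGeometry("wt_6mpf"))
  gP <- geometryValues(makeEyeGeometry("prss56_6mpf"))
  rre <- function(v) relativeRefractiveError(
    v[["lensDiameter"]] / 2, v[["lensDiameter"]] / 2 + v[["vcd"]])
  expect_gt(rre(gP), rre(gW))
})
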