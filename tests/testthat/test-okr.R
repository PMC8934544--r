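test_that("saccade detection counts sawtooth resets", {
  tr <- synthOkrTrace(20, 1, 20, duration = 30, noiseSd = 0)
  n <- length(detectSaccades(tr))
  expect_true(abs(n - 30) <= 1)

  ramp <- synthOkrTrace(20, 40, 20, duration = 30, noiseSd = 0)  # no resets
  expect_length(detectSaccades(ramp), 0)

  expect_length(detectSaccades(tr, velocityThreshold = 1e5), 0)
})

test_that("slow-phase velocity is recovered across the tested range", {
  tr <- synthOkrTrace(20, 1, 20, duration = 60, noiseSd = 0)
  spv <- slowPhaseVelocity(tr)
  expect_lt(abs(spv$velocity - 20), 0.1)
  expect_false(spv$noResponse)

  flat <- synthOkrTrace(0, 1, 20, duration = 60, noiseSd = 0)
  expect_true(slowPhaseVelocity(flat)$noResponse)

  noisy <- synthOkrTrace(20, 1, 20, duration = 60, noiseSd = 0.5, seed = 1)
  expect_lt(abs(slowPhaseVelocity(noisy)$velocity - 20) / 20, 0.05)

  # parameter recovery bias < 5% over the velocity range, default noise
  for (v in c(5, 10, 15, 20)) {
    rec <- sapply(1:3, function(i) {
      tr <- synthOkrTrace(v, 20 / v, 20, duration = 60, noiseSd = 0.5,
                          seed = 10 * v + i)
      slowPhaseVelocity(tr)$velocity
    })
    expect_lt(abs(mean(rec) - v) / v, 0.05)
  }
})

test_that("optokinetic gain is a scale-invariant speed ratio", {
  expect_equal(optokineticGain(20, 20), 1)
  expect_equal(optokineticGain(10, 20), 0.5)
  expect_equal(optokineticGain(0, 20), 0)
  expect_equal(optokineticGain(-10, 20), 0.5)  # direction-agnostic
  expect_error(optokineticGain(10, 0), "non-zero")
  for (c in c(0.5, 2, 7)) {
    expect_equal(optokineticGain(13 * c, 20 * c), optokineticGain(13, 20))
  }
})

test_that("ETM counting bins saccade-delimited cycles per 15 s", {
  tr <- synthOkrTrace(20, 1, 20, duration = 60, noiseSd = 0)
  sac <- detectSaccades(tr)
  etm <- countEtms(tr, sac)
  expect_length(etm, 4)
  expect_true(all(abs(etm - 15) <= 1))
  # totals are conserved: every saccade in a retained bin is counted once
  expect_equal(sum(etm), sum(sac < 60))

  tr61 <- synthOkrTrace(20, 1, 20, duration = 61, noiseSd = 0)
  expect_length(countEtms(tr61), 4)  # trailing second dropped

  flat <- synthOkrTrace(0, 1, 20, duration = 60, noiseSd = 0)
  expect_equal(countEtms(flat), rep(0L, 4))

  short <- synthOkrTrace(20, 1, 20, duration = 30, sampleRate = 60)
  expect_error(countEtms(short, window = 45), "shorter")
})

test_that("eye tracking recovers rendered angles and flags bad input", {
  th <- 12 * sin(2 * pi * (0:149) / 75)
  frames <- renderEyeFrames(th)
  tr <- trackEyeAngles(frames)
  expect_lt(sqrt(mean((tr@angleLeft - th)^2)), 1)
  expect_lt(sqrt(mean((tr@angleRight - th)^2)), 1)

  static <- renderEyeFrames(rep(3, 60))
  trs <- trackEyeAngles(static)
  vel <- diff(trs@angleLeft) * 60
  expect_lt(max(abs(vel)), 1)

  oneEye <- lapply(1:60, function(i) {
    f <- renderEyeFrames(0)[[1]]
    f[, 49:96] <- 200  # erase the right eye
    f
  })
  expect_error(trackEyeAngles(oneEye), "frames")
})

test_that("per-fish OKR analysis flags non-responders with zero ETMs", {
  tr <- synthOkrTrace(15, 20 / 15, 20, duration = 60, noiseSd = 0.5,
                      seed = 5)
  res <- analyzeOkr(tr)
  expect_false(res@noResponse)
  expect_lt(abs(res@gainTn - 0.75), 0.05)
  expect_lt(abs(res@gainNt - 0.75), 0.05)
  expect_gt(sum(res@etmPer15s), 0)

  flat <- synthOkrTrace(0, 1, 20, duration = 60, noiseSd = 0.3, seed = 6)
  resF <- analyzeOkr(flat)
  expect_true(resF@noResponse)
  expect_true(is.na(resF@gainTn) && is.na(resF@gainNt))
  expect_equal(sum(resF@etmPer15s), 0L)
})

test_that("angle traces survive the CSV round trip", {
  tr <- synthOkrTrace(10, 2, 20, duration = 30, noiseSd = 0.2, seed = 9)
  p <- tempfile(fileext = ".csv")
  writeAngleTraceCsv(tr, p)
  tr2 <- readAngleTraceCsv(p)
  expect_equal(tr2@angleLeft, tr@angleLeft, tolerance = 1e-8)
  expect_equal(tr2@sampleRate, tr@sampleRate)
  expect_equal(tr2@stimulus$drum_velocity, tr@stimulus$drum_velocity)
  # bin counting survives float error in the reconstructed time column
  expect_length(countEtms(tr2), length(countEtms(tr)))
})
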