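test_that("geometry presets encode the measured genotype differences", {
  delta <- function(mut, wt, field) {
    geometryValues(makeEyeGeometry(mut))[[field]] -
      geometryValues(makeEyeGeometry(wt))[[field]]
  }
  axDelta <- function(mut, wt)
    axialLength(makeEyeGeometry(mut)) - axialLength(makeEyeGeometry(wt))

  # wild-type retinal thinning with age
  expect_equal(geometryValues(makeEyeGeometry("wt_2mpf"))[["retinalThickness"]], 152)
  expect_equal(geometryValues(makeEyeGeometry("wt_4mpf"))[["retinalThickness"]], 137)
  expect_equal(geometryValues(makeEyeGeometry("wt_6mpf"))[["retinalThickness"]], 126)

  # prss56: axial deltas are the headline endpoints and match exactly
  expect_equal(axDelta("prss56_2mpf", "wt_2mpf"), -157)
  expect_equal(axDelta("prss56_4mpf", "wt_4mpf"), -260)
  expect_equal(axDelta("prss56_6mpf", "wt_6mpf"), -330)

  # per-component prss56 deltas (VCD absorbs the rounding residual of the
  # printed per-panel values, so it is checked to 3 um)
  expect_equal(delta("prss56_6mpf", "wt_6mpf", "cornealThickness"), 5)
  expect_equal(delta("prss56_6mpf", "wt_6mpf", "acd"), -6)
  expect_equal(delta("prss56_6mpf", "wt_6mpf", "lensDiameter"), -73)
  expect_equal(delta("prss56_6mpf", "wt_6mpf", "retinalThickness"), 32)
  expect_lt(abs(delta("prss56_6mpf", "wt_6mpf", "vcd") - (-289)), 3)
  expect_equal(delta("prss56_2mpf", "wt_2mpf", "lensDiameter"), -32)
  expect_lt(abs(delta("prss56_2mpf", "wt_2mpf", "vcd") - (-132)), 4)
  expect_equal(delta("prss56_2mpf", "wt_2mpf", "rpeThickness"), 3)
  expect_equal(delta("prss56_4mpf", "wt_4mpf", "acd"), -7)
  expect_equal(delta("prss56_4mpf", "wt_4mpf", "rpeThickness"), -5)

  # fbn1: lens subluxation deepens the anterior chamber; no lens change
  expect_equal(delta("fbn1_2mpf", "wt_2mpf", "lensDiameter"), 0)
  expect_equal(delta("fbn1_2mpf", "wt_2mpf", "acd"), 3)
  expect_equal(delta("fbn1_4mpf", "wt_4mpf", "acd"), 11)
  expect_equal(delta("fbn1_6mpf", "wt_6mpf", "acd"), 27)
  expect_equal(delta("fbn1_6mpf", "wt_6mpf", "vcd"), -51)
  expect_equal(delta("fbn1_6mpf", "wt_6mpf", "retinalThickness"), 10)

  expect_error(makeEyeGeometry("wt_12mpf"), "known presets")
})

test_that("OCT forward model is seed-deterministic and bounded by depth", {
  g <- makeEyeGeometry("wt_6mpf")
  cfg0 <- testRenderConfig(speckleSd = 0)
  v1 <- renderOctVolume(g, cfg0, seed = 1)
  v2 <- renderOctVolume(g, cfg0, seed = 2)
  expect_identical(v1@data, v2@data)  # noiseless renders ignore the seed

  cfgN <- testRenderConfig(speckleSd = 800)
  n1 <- renderOctVolume(g, cfgN, seed = 5)
  n2 <- renderOctVolume(g, cfgN, seed = 5)
  n3 <- renderOctVolume(g, cfgN, seed = 6)
  expect_identical(n1@data, n2@data)
  expect_false(identical(n1@data, n3@data))

  shallow <- octRenderConfig(dims = c(41L, 41L, 200L))
  expect_error(renderOctVolume(g, shallow), "exceeds volume depth")
})

test_that("interface depths follow the optical-path model", {
  g <- eyeGeometry(30, 35, 100, 300, 126, 14, 1100, 1100)
  idx <- refractiveIndices()
  zb <- zfocular:::opticalBoundaries(g, idx, 0)
  # lens occupies geometric thickness x 1.40 of optical path
  expect_equal(unname(zb["lens_posterior"] - zb["lens_anterior"]),
               100 * 1.40)
  expect_equal(unname(zb["cornea_inner"]), 30 * 1.33)
  expect_equal(unname(zb["rpe_outer"]),
               30 * 1.33 + 35 * 1.34 + 100 * 1.40 + 300 * 1.34 +
                 126 * 1.38 + 14 * 1.38)
})

test_that("pupil frame forward model has the stated ramp geometry", {
  f0 <- renderPupilFrame(0, noiseSd = 0)
  inside <- f0[30:66, 30:66]  # strict interior, away from the soft rim
  expect_equal(stats::sd(inside), 0)  # uniform disk at slope 0

  fp <- renderPupilFrame(30, noiseSd = 0)
  fn <- renderPupilFrame(-30, noiseSd = 0)
  top <- 1:47; bottom <- 49:96
  expect_gt(mean(fp[bottom, 48][fp[bottom, 48] > 100]),
            mean(fp[top, 48][fp[top, 48] > 100]))
  expect_gt(mean(fn[top, 48][fn[top, 48] > 100]),
            mean(fn[bottom, 48][fn[bottom, 48] > 100]))

  expect_error(renderPupilFrame(0, radius = 4), "radius")
  expect_error(renderPupilFrame(0, center = c(5, 48), radius = 30), "fit")

  s1 <- renderPupilFrame(10, noiseSd = 1.5, seed = 11)
  s2 <- renderPupilFrame(10, noiseSd = 1.5, seed = 11)
  expect_identical(s1, s2)
})

test_that("sawtooth trace generator matches its construction", {
  tr <- synthOkrTrace(20, 1, 20, duration = 60, noiseSd = 0)
  expect_lt(max(abs(tr@angleLeft)), 21)  # balanced sawtooth stays bounded
  expect_identical(tr@angleLeft, tr@angleRight)

  expect_error(synthOkrTrace(20, saccadeInterval = 0.02, sampleRate = 60),
               "saccadeInterval")
  expect_error(synthOkrTrace(20, duration = 10), "duration")
  expect_error(synthOkrTrace(20, sampleRate = 10), "sampleRate")

  flat <- synthOkrTrace(0, 1, 20, duration = 60, noiseSd = 0)
  expect_length(detectSaccades(flat), 0)

  a <- synthOkrTrace(15, 1.5, 20, duration = 40, noiseSd = 0.5, seed = 2)
  b <- synthOkrTrace(15, 1.5, 20, duration = 40, noiseSd = 0.5, seed = 2)
  expect_identical(a@angleLeft, b@angleLeft)
})

test_that("tonometer reading generator is seeded and validated", {
  expect_equal(synthIopReadings(12, sd = 0, n = 6), rep(12, 6))
  r <- synthIopReadings(12, sd = 1, n = 6, seed = 3)
  expect_identical(r, synthIopReadings(12, sd = 1, n = 6, seed = 3))
  # CLT bound: sample mean within 3 standard errors
  expect_lt(abs(mean(synthIopReadings(12, 1, 600, seed = 4)) - 12),
            3 * 1 / sqrt(600))
  expect_error(synthIopReadings(12, 1, 0), "n must be")
})

test_that("cohort generation writes consistent, reproducible metadata", {
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  unlink(c(d1, d2), recursive = TRUE)
  spec <- cohortSpec(c("wt_6mpf", "prss56_6mpf"), nFishPerGenotype = 5,
                     seed = 11)
  makeCohort(spec, d1, assays = "iop")
  makeCohort(spec, d2, assays = "iop")

  meta <- read.csv(file.path(d1, "metadata.csv"))
  expect_equal(nrow(meta), 2 * 5 * 2)               # eyes
  expect_equal(length(unique(meta$fish_id)), 10)    # fish rows
  expect_identical(readLines(file.path(d1, "metadata.csv")),
                   readLines(file.path(d2, "metadata.csv")))

  man <- readManifest(d1)
  expect_equal(length(man$files), 20)
  # body lengths drawn from a common distribution: the 1% matching rule
  # holds by construction
  expect_true(sizeMatchFilter(meta, reference = "wt_6mpf")$pass)
})
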