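idxDefault <- refractiveIndices()

test_that("noiseless renders are segmented to sub-pixel accuracy", {
  cfg <- testRenderConfig(speckleSd = 0)
  for (preset in c("wt_6mpf", "prss56_6mpf")) {
    g <- makeEyeGeometry(preset)
    vol <- renderOctVolume(g, cfg, idxDefault)
    bset <- segmentAxialBoundaries(vol)
    truth <- zfocular:::opticalBoundaries(g, idxDefault, cfg$zOffset)
    # every interface within one z pixel (2 um optical)
    expect_lt(max(abs(boundaryPositions(bset) - truth)), cfg$zPitch)

    comp <- correctOpticalPath(bset, idxDefault)
    expect_lt(max(abs(comp - geometryValues(g)[1:6])), cfg$zPitch)
  }
})

test_that("optical-path correction divides by the compartment index", {
  z <- cumsum(c(50, 40, 47, 140, 402, 174, 19))
  names(z) <- zfocular:::.BOUNDARY_NAMES
  bset <- new("BoundarySet", positions = z, axis = c(1L, 1L), zPitch = 2)
  comp <- correctOpticalPath(bset, idxDefault)
  expect_equal(unname(comp[["lens_diameter"]]), 140 / 1.40)
  expect_equal(unname(comp[["corneal_thickness"]]), 40 / 1.33)

  ones <- refractiveIndices(1, 1, 1, 1, 1, 1)
  expect_equal(unname(correctOpticalPath(bset, ones)), unname(diff(z)))

  # non-monotone boundary sets are rejected outright
  bad <- z; bad[3] <- bad[2] - 1
  expect_error(new("BoundarySet", positions = bad, axis = c(1L, 1L),
                   zPitch = 2), "increase")
})

test_that("index sensitivity: a larger index shrinks that compartment only", {
  cfg <- testRenderConfig(speckleSd = 0)
  vol <- renderOctVolume(makeEyeGeometry("wt_6mpf"), cfg, idxDefault)
  bset <- segmentAxialBoundaries(vol)
  hiLens <- refractiveIndices(lens = 1.45)
  a <- correctOpticalPath(bset, idxDefault)
  b <- correctOpticalPath(bset, hiLens)
  expect_lt(b[["lens_diameter"]], a[["lens_diameter"]])
  expect_equal(a[-3], b[-3])
})

test_that("biometry is additive and scales with the geometry", {
  cfg <- testRenderConfig(speckleSd = 0)
  g1 <- eyeGeometry(30, 35, 450, 280, 130, 14, 1000, 1000)
  b1 <- computeBiometry(renderOctVolume(g1, cfg), idxDefault)
  df <- as.data.frame(b1)
  expect_equal(df$axial_length,
               df$corneal_thickness + df$acd + df$lens_diameter + df$vcd +
                 df$retinal_thickness + df$rpe_thickness)

  sc <- 0.8
  v <- geometryValues(g1) * sc
  g2 <- eyeGeometry(v[1], v[2], v[3], v[4], v[5], v[6], v[7], v[8])
  b2 <- computeBiometry(renderOctVolume(g2, cfg), idxDefault)
  expect_lt(abs(axialLength(b2) - sc * axialLength(b1)), 2 * cfg$zPitch)
  expect_lt(abs(b2@vcd - sc * b1@vcd), 2 * cfg$zPitch)
})

test_that("speckle-level noise leaves boundary errors below 2 um", {
  cfg <- testRenderConfig(speckleSd = 800)
  g <- makeEyeGeometry("wt_6mpf")
  truth <- zfocular:::opticalBoundaries(g, idxDefault, cfg$zOffset)
  errs <- sapply(1:4, function(i) {
    vol <- renderOctVolume(g, cfg, idxDefault, seed = 100 + i)
    abs(boundaryPositions(segmentAxialBoundaries(vol)) - truth)
  })
  expect_lt(mean(errs), 2)
})

test_that("eye volume reduces to the sphere formula for a spherical eye", {
  ones <- refractiveIndices(1, 1, 1, 1, 1, 1)
  g <- eyeGeometry(30, 30, 500, 300, 126, 14, 1000, 1000)  # axial sum 1000
  cfg <- octRenderConfig(dims = c(101L, 101L, 560L), lateralPitch = 12,
                         speckleSd = 0)
  b <- computeBiometry(renderOctVolume(g, cfg, ones), ones)
  expect_lt(abs(b@eyeVolume - (pi / 6) * 1000^3) / ((pi / 6) * 1000^3), 0.05)
})

test_that("a collapsed anterior chamber reports ACD 0 with a qc flag", {
  cfg <- testRenderConfig(speckleSd = 0)
  g <- eyeGeometry(30, 1, 500, 300, 126, 14, 1100, 1100)
  b <- computeBiometry(renderOctVolume(g, cfg), idxDefault)
  expect_lt(b@acd, 0.01)
  expect_true("acd_at_floor" %in% b@qcFlags)
  expect_lt(abs(b@lensDiameter - 500), 2)
})

test_that("contrast-free volumes are rejected", {
  flat <- new("OctVolume", data = array(7, c(15, 15, 60)), zPitch = 2,
              lateralPitch = 20)
  expect_error(segmentAxialBoundaries(flat), "no interfaces found")
})
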