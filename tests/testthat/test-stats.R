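# Independent Welch ANOVA oracle: direct transcription of the published
# formula (weights n/s^2, weighted grand mean, Welch-Satterthwaite df).
welchOracle <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  w <- n / v
  W <- sum(w)
  mw <- sum(w * m) / W
  A <- sum(w * (m - mw)^2) / (k - 1)
  S <- sum((1 - w / W)^2 / (n - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * S
  F <- A / B
  df2 <- (k^2 - 1) / (3 * S)
  list(F = F, df1 = k - 1, df2 = df2,
       p = pf(F, k - 1, df2, lower.tail = FALSE))
}

test_that("CS mixed model equals the fish-means GLS oracle on balanced data", {
  set.seed(101)
  cases <- list(
    list(nFish = 10, effect = 5, sigmaFish = 3, sigmaEye = 1),
    list(nFish = 6, effect = 0, sigmaFish = 1, sigmaEye = 2),
    list(nFish = 15, effect = -40, sigmaFish = 8, sigmaEye = 4))
  for (cs in cases) {
    tab <- balancedTable(cs$nFish, cs$effect, cs$sigmaFish, cs$sigmaEye)
    fit <- fitCsMixed(tab, "m", reference = "wt")
    ora <- fishMeansOracle(tab, "wt")
    expect_equal(effectSize(fit)[["mut"]], ora$effect, tolerance = 1e-6)
    expect_equal(pValue(fit)[["mut"]], ora$p, tolerance = 1e-4)
    expect_equal(fit@df[["mut"]], ora$df)
    expect_true(fit@icc >= 0 && fit@icc <= 1)
  }
})

test_that("zero within-fish variance reduces exactly to the fish-means t-test", {
  set.seed(7)
  tab <- balancedTable(8, 3, sigmaFish = 2, sigmaEye = 1)
  fm <- tapply(tab$value, tab$fish_id, mean)
  tab$value <- fm[tab$fish_id]   # both eyes identical per fish
  fit <- fitCsMixed(tab, "m", reference = "wt")
  ora <- fishMeansOracle(tab, "wt")
  expect_equal(effectSize(fit)[["mut"]], ora$effect, tolerance = 1e-8)
  expect_equal(pValue(fit)[["mut"]], ora$p, tolerance = 1e-6)
})

test_that("degenerate and invalid designs are handled explicitly", {
  tab <- balancedTable(5, 0, 1, 1)
  tab$value <- 7
  fit <- fitCsMixed(tab, "m", reference = "wt")
  expect_equal(effectSize(fit)[["mut"]], 0)
  expect_equal(fit@sigmaFish2, 0)
  expect_equal(fit@sigmaEye2, 0)

  expect_error(fitCsMixed(tab[tab$genotype == "wt", ], "m", "wt"),
               "2 genotypes")
  expect_error(fitCsMixed(tab, "m", reference = "absent"), "reference")
  small <- balancedTable(2, 0, 1, 1)
  expect_error(fitCsMixed(small, "m", "wt"), "3 fish")
  expect_error(fitCsMixed(tab, "nope", "wt"), "no rows")

  three <- tab
  three$value[1] <- 8
  extra <- three[1:2, ]; extra$eye <- c("L2", "R2")
  expect_error(fitCsMixed(rbind(three, extra), "m", "wt"),
               "two eyes")
})

test_that("estimated effect is shift-equivariant", {
  set.seed(33)
  tab <- balancedTable(10, 4, 3, 1)
  base <- effectSize(fitCsMixed(tab, "m", "wt"))[["mut"]]
  tab2 <- tab
  tab2$value[tab2$genotype == "mut"] <- tab2$value[tab2$genotype == "mut"] + 11
  shifted <- effectSize(fitCsMixed(tab2, "m", "wt"))[["mut"]]
  expect_equal(shifted, base + 11, tolerance = 1e-6)
})

test_that("Welch ANOVA matches the published formula and the t-test identity", {
  set.seed(55)
  g3 <- list(rnorm(8, 0, 1), rnorm(12, 0.8, 2.5), rnorm(6, -0.5, 0.6))
  ours <- welchAnova(g3)
  ora <- welchOracle(g3)
  expect_equal(ours$F, ora$F, tolerance = 1e-6)
  expect_equal(ours$df2, ora$df2, tolerance = 1e-6)
  expect_equal(ours$p, ora$p, tolerance = 1e-6)

  # two groups: F equals the square of the Welch t statistic
  a <- rnorm(9, 0, 1); b <- rnorm(14, 1, 2)
  w2 <- welchAnova(list(a, b))
  tt <- t.test(a, b)
  expect_equal(w2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(w2$df2, unname(tt$parameter), tolerance = 1e-9)

  same <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3))
  res <- welchAnova(same)
  expect_lt(res$F, 1e-12)
  expect_gt(res$p, 0.999)

  expect_error(welchAnova(list(rnorm(5))), "2 groups")
  expect_error(welchAnova(list(rnorm(5), 3)), "2 values")
})

test_that("body-length matching applies the inclusive 1% rule", {
  mk <- function(mutMean) data.frame(
    fish_id = sprintf("f%02d", 1:20),
    genotype = rep(c("wt", "mut"), each = 10),
    body_length = c(rep(30, 10), rep(mutMean, 10)))
  expect_true(sizeMatchFilter(mk(30), "wt")$pass)
  expect_true(sizeMatchFilter(mk(30 * 1.01), "wt")$pass)   # boundary included
  expect_false(sizeMatchFilter(mk(30 * 1.015), "wt")$pass)
  expect_false(sizeMatchFilter(mk(30 * 0.985), "wt")$pass)
  expect_error(sizeMatchFilter(mk(30), "missing"), "reference")
  bad <- mk(30); bad$body_length[3] <- NA
  expect_error(sizeMatchFilter(bad, "wt"), "missing")
})

test_that("Monte-Carlo power is calibrated at the null and saturates", {
  null <- powerSim(0, 3, 1, 10, nReps = 400, seed = 1)
  expect_lt(abs(null$power - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 0.01)

  sat <- powerSim(10 * sqrt(10), 3, 1, 10, nReps = 200, seed = 2)
  expect_gt(sat$power, 0.99)

  pLow <- powerSim(3, 3, 1, 6, nReps = 400, seed = 3)$power
  pMoreFish <- powerSim(3, 3, 1, 20, nReps = 400, seed = 4)$power
  pMoreEffect <- powerSim(6, 3, 1, 6, nReps = 400, seed = 5)$power
  expect_gt(pMoreFish, pLow)
  expect_gt(pMoreEffect, pLow)

  # full REML route agrees with the closed-form route within MC error
  a <- powerSim(4, 3, 1, 8, nReps = 150, seed = 6)$power
  b <- powerSim(4, 3, 1, 8, nReps = 150, seed = 6, method = "reml")$power
  expect_lt(abs(a - b), 0.12)

  expect_error(powerSim(1, 0, 1, 10), "positive")
  expect_error(powerSim(1, 1, 1, 10, nReps = 50), "nReps")
})
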