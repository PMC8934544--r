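# Shared fixtures: a reduced-footprint render configuration for fast tests
# (the full instrument field of view is exercised in the acceptance suite)
# and a balanced two-eyes-per-fish measurement table generator.

testRenderConfig <- function(speckleSd = 0) {
  octRenderConfig(dims = c(75L, 75L, 920L), speckleSd = speckleSd)
}

balancedTable <- function(nFish = 10, effect = 0, sigmaFish = 3,
                          sigmaEye = 1, metric = "m",
                          genotypes = c("wt", "mut")) {
  nf <- nFish
  data.frame(
    fish_id = rep(sprintf("%s_f%02d", rep(genotypes, each = nf),
                          rep(1:nf, 2)), each = 2),
    eye = rep(c("L", "R"), 2 * nf),
    genotype = rep(genotypes, each = 2 * nf),
    metric_name = metric,
    value = rep(c(rep(0, nf), rep(effect, nf)), each = 2) +
      rep(rnorm(2 * nf, 0, sigmaFish), each = 2) +
      rnorm(4 * nf, 0, sigmaEye),
    stringsAsFactors = FALSE)
}

# closed-form oracle for the balanced CS design: pooled t-test on fish means
fishMeansOracle <- function(tab, reference) {
  fm <- tapply(tab$value, tab$fish_id, mean)
  g <- tapply(tab$genotype, tab$fish_id, `[`, 1)
  other <- setdiff(unique(g), reference)
  tt <- t.test(fm[g == other], fm[g == reference], var.equal = TRUE)
  list(effect = unname(diff(rev(tt$estimate))), p = tt$p.value,
       t = unname(tt$statistic), df = unname(tt$parameter))
}
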