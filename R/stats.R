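#' Significance stars for a p-value
#'
#' @param p p-value(s).
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `"ns"` otherwise (`""` for `NA`).
#' @export
pStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else "ns"
  }, character(1))
}

.checkMeasurementTable <- function(table, metric = NULL) {
  need <- c("fish_id", "eye", "genotype", "metric_name", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("measurement table lacks columns: ", paste(miss, collapse = ", "))
  if (!is.null(metric)) {
    table <- table[table$metric_name == metric, , drop = FALSE]
    if (!nrow(table)) stop("no rows for metric '", metric, "'")
  }
  tab <- table(paste(table$fish_id, table$metric_name))
  if (any(tab > 2)) stop("more than two eyes per fish for a metric")
  table
}

#' Fit the compound-symmetry repeated-measures mixed model
#'
#' The two eyes of one fish are repeated measures: the model is
#' `value = intercept + genotype + (1 | fish) + residual`, fitted by REML.
#' The random fish intercept induces a compound-symmetry covariance between
#' eyes with non-negativity-constrained variance components. Genotype is a
#' between-fish effect, so fixed-effect tests use the between-fish degrees
#' of freedom `n_fish - n_genotypes`; in the balanced two-eyes design this
#' coincides with the closed-form GLS solution (a pooled t-test on fish
#' means for two genotypes).
#'
#' @param table long-format data.frame with columns `fish_id`, `eye`,
#'   `genotype`, `metric_name`, `value` (and optionally `body_length`,
#'   `age_label`).
#' @param metric metric to analyze (`metric_name` value).
#' @param reference reference (wild-type) genotype label.
#' @return a [MixedFit-class]; coefficients are named by non-reference
#'   genotype. Degenerate tables with zero total variance return a zero
#'   effect with `NA` p-values.
#' @examples
#' tab <- data.frame(
#'   fish_id = rep(sprintf("f%02d", 1:10), each = 2),
#'   eye = rep(c("L", "R"), 10),
#'   genotype = rep(c("wt", "mut"), each = 10),
#'   metric_name = "axial_length",
#'   value = c(rnorm(10, 1000, 5), rnorm(10, 900, 5)))
#' fitCsMixed(tab, "axial_length", reference = "wt")
#' @export
fitCsMixed <- function(table, metric, reference) {
  d <- .checkMeasurementTable(table, metric)
  d <- d[is.finite(d$value), , drop = FALSE]
  genos <- unique(d$genotype)
  if (length(genos) < 2) stop("need >= 2 genotypes (singular design)")
  if (!reference %in% genos)
    stop("reference genotype '", reference, "' not present")
  nPerG <- vapply(split(d$fish_id, d$genotype),
                  function(f) length(unique(f)), integer(1))
  if (any(nPerG < 3)) stop("need >= 3 fish per genotype")
  d$genotype <- stats::relevel(factor(d$genotype), ref = reference)
  d$fish_id <- factor(d$fish_id)
  nFish <- nlevels(d$fish_id)
  nEyes <- nrow(d)
  dfBetween <- nFish - length(genos)
  coefNames <- levels(d$genotype)[-1]

  if (stats::var(d$value) == 0) {
    z <- stats::setNames(rep(0, length(coefNames)), coefNames)
    na <- stats::setNames(rep(NA_real_, length(coefNames)), coefNames)
    return(new("MixedFit", metric = metric, reference = reference,
               effectSize = z, se = z, tValue = na, df = na, pValue = na,
               sigmaFish2 = 0, sigmaEye2 = 0, icc = NA_real_,
               nFish = nFish, nEyes = as.integer(nEyes), converged = TRUE))
  }

  fit <- tryCatch(
    nlme::lme(value ~ genotype, random = ~ 1 | fish_id, data = d,
              method = "REML",
              control = nlme::lmeControl(opt = "optim",
                                         returnObject = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # non-convergence: fall back to the closed-form between-fish analysis
    fm <- stats::aggregate(value ~ fish_id + genotype, d, mean)
    lmfit <- stats::lm(value ~ genotype, fm)
    sm <- summary(lmfit)$coefficients
    rows <- paste0("genotype", coefNames)
    eff <- stats::setNames(sm[rows, 1], coefNames)
    se <- stats::setNames(sm[rows, 2], coefNames)
    tv <- eff / se
    pv <- 2 * stats::pt(-abs(tv), dfBetween)
    return(new("MixedFit", metric = metric, reference = reference,
               effectSize = eff, se = se, tValue = tv,
               df = stats::setNames(rep(dfBetween, length(eff)), coefNames),
               pValue = pv, sigmaFish2 = NA_real_, sigmaEye2 = NA_real_,
               icc = NA_real_, nFish = nFish, nEyes = as.integer(nEyes),
               converged = FALSE))
  }

  tTab <- summary(fit)$tTable
  rows <- paste0("genotype", coefNames)
  eff <- stats::setNames(tTab[rows, "Value"], coefNames)
  se <- stats::setNames(tTab[rows, "Std.Error"], coefNames)
  tv <- eff / se
  df <- stats::setNames(rep(dfBetween, length(eff)), coefNames)
  pv <- 2 * stats::pt(-abs(tv), df)
  vc <- nlme::VarCorr(fit)
  sigFish2 <- suppressWarnings(as.numeric(vc["(Intercept)", "Variance"]))
  sigEye2 <- fit$sigma^2
  if (!is.finite(sigFish2)) sigFish2 <- 0
  if (!is.finite(sigEye2)) sigEye2 <- 0
  icc <- if (sigFish2 + sigEye2 > 0) sigFish2 / (sigFish2 + sigEye2)
         else NA_real_
  new("MixedFit", metric = metric, reference = reference,
      effectSize = eff, se = se, tValue = tv, df = df, pValue = pv,
      sigmaFish2 = max(0, sigFish2), sigmaEye2 = sigEye2, icc = icc,
      nFish = nFish, nEyes = as.integer(nEyes), converged = TRUE)
}

#' Welch's heteroscedastic analysis of variance
#'
#' Welch's F statistic with Welch-Satterthwaite denominator degrees of
#' freedom, for per-fish metrics (optokinetic gain, ETM counts, body
#' length) whose group variances need not be equal.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values with
#'   positive variance in at least one group).
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
welchAnova <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  res <- stats::oneway.test(y ~ g, var.equal = FALSE)
  list(F = unname(res$statistic), df1 = unname(res$parameter[1]),
       df2 = unname(res$parameter[2]), p = unname(res$p.value))
}

#' Body-length matching filter
#'
#' Cohorts are admissible for intraocular biometry comparison only when
#' each mutant group's mean body length is within `tolerance` (1% by
#' default, inclusive) of the reference group's mean, isolating intraocular
#' from extraocular (whole-body) size differences.
#'
#' @param table data.frame with columns `fish_id`, `genotype` and
#'   `body_length` (one value per fish; per-eye tables are collapsed).
#' @param reference reference genotype label.
#' @param tolerance maximum relative difference of group means.
#' @return list with `pass` (logical) and `report` (per-genotype data.frame
#'   with mean body length, relative difference and pass flag).
#' @export
sizeMatchFilter <- function(table, reference, tolerance = 0.01) {
  need <- c("fish_id", "genotype", "body_length")
  if (!all(need %in% names(table)))
    stop("table lacks columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  if (any(!is.finite(table$body_length)))
    stop("body_length missing for some fish")
  fish <- unique(table[, c("fish_id", "genotype", "body_length")])
  means <- tapply(fish$body_length, fish$genotype, mean)
  if (!reference %in% names(means))
    stop("reference genotype '", reference, "' not present")
  refMean <- means[[reference]]
  rel <- abs(means - refMean) / refMean
  report <- data.frame(genotype = names(means),
                       mean_body_length = as.numeric(means),
                       rel_diff = as.numeric(rel),
                       pass = as.numeric(rel) <= tolerance + 1e-12,
                       row.names = NULL)
  list(pass = all(report$pass[report$genotype != reference]),
       report = report)
}

#' Monte-Carlo power for the two-eyes-per-fish design
#'
#' Simulates balanced two-genotype cohorts under the compound-symmetry
#' model (fish random intercept plus eye-level residual) and reports the
#' fraction of replicates in which the genotype effect is detected at
#' `alpha`. In this balanced design the REML compound-symmetry test is
#' identical to the pooled t-test on fish means, which the simulation uses
#' for speed; set `method = "reml"` to fit the full mixed model per
#' replicate instead.
#'
#' @param effect true genotype effect, metric units.
#' @param sigmaFish between-fish SD (> 0).
#' @param sigmaEye between-eye (residual) SD (> 0).
#' @param nFishPerGroup fish per genotype (two eyes each).
#' @param alpha significance level.
#' @param nReps Monte-Carlo replicates (>= 100).
#' @param seed integer seed.
#' @param method `"closed_form"` (default) or `"reml"`.
#' @return list with `power`, `mcError` (binomial standard error), `nReps`.
#' @export
powerSim <- function(effect, sigmaFish, sigmaEye, nFishPerGroup,
                     alpha = 0.05, nReps = 200, seed = NULL,
                     method = c("closed_form", "reml")) {
  if (sigmaFish <= 0 || sigmaEye <= 0)
    stop("variance components must be positive")
  if (nReps < 100) stop("nReps must be >= 100")
  method <- match.arg(method)
  nf <- nFishPerGroup
  withSeed(seed, {
    hits <- vapply(seq_len(nReps), function(r) {
      fishMeanSd <- sqrt(sigmaFish^2 + sigmaEye^2 / 2)
      if (method == "closed_form") {
        m1 <- stats::rnorm(nf, 0, fishMeanSd)
        m2 <- stats::rnorm(nf, effect, fishMeanSd)
        sp2 <- (stats::var(m1) + stats::var(m2)) / 2
        tv <- (mean(m2) - mean(m1)) / sqrt(sp2 * 2 / nf)
        p <- 2 * stats::pt(-abs(tv), 2 * nf - 2)
      } else {
        tab <- data.frame(
          fish_id = rep(sprintf("f%03d", 1:(2 * nf)), each = 2),
          eye = rep(c("L", "R"), 2 * nf),
          genotype = rep(c("a_ref", "mut"), each = 2 * nf),
          metric_name = "m",
          value = rep(c(rep(0, nf), rep(effect, nf)), each = 2) +
            rep(stats::rnorm(2 * nf, 0, sigmaFish), each = 2) +
            stats::rnorm(4 * nf, 0, sigmaEye))
        p <- pValue(fitCsMixed(tab, "m", reference = "a_ref"))[["mut"]]
      }
      p < alpha
    }, logical(1))
    power <- mean(hits)
    list(power = power,
         mcError = sqrt(power * (1 - power) / nReps), nReps = nReps)
  })
}
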