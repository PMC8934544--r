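#' Default pipeline configuration
#'
#' All assay constants in one place: refractive indices for the OCT
#' correction, the photorefraction calibration, the focal-length
#' coefficients of the relative refractive error, the OKR stimulus and
#' thresholds, the tonometry protocol count, and the statistical settings.
#'
#' @return nested list of class `PipelineConfig`.
#' @export
defaultPipelineConfig <- function() {
  structure(list(
    indices = list(cornea = 1.33, lens = 1.40, anterior_chamber = 1.34,
                   vitreous = 1.34, retina = 1.38, rpe = 1.38),
    refraction = list(gain = 0.5, offset = 0),
    rre = list(slope_coeff = 2.182, intercept = 11.699),
    okr = list(drum_velocity = 20, spatial_frequency = 0.15,
               saccade_threshold = 100, smooth_window = 0.2,
               min_segment = 0.3, r2_min = 0.8, etm_window = 15),
    iop = list(expected_n = 6),
    stats = list(alpha = 0.05, size_tolerance = 0.01,
                 reference_prefix = "wt")
  ), class = "PipelineConfig")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a `PipelineConfig` list.
#' @param path YAML path.
#' @return `writePipelineConfig` returns `path` invisibly;
#'   `readPipelineConfig` returns the configuration with defaults filled in
#'   for missing keys.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- unclass(defaultPipelineConfig())
  for (k in names(usr)) {
    if (is.list(cfg[[k]]) && is.list(usr[[k]])) {
      for (kk in names(usr[[k]])) cfg[[k]][[kk]] <- usr[[k]][[kk]]
    } else cfg[[k]] <- usr[[k]]
  }
  structure(cfg, class = "PipelineConfig")
}

.indicesFromConfig <- function(config) {
  ix <- config$indices
  refractiveIndices(ix$cornea, ix$lens, ix$anterior_chamber, ix$vitreous,
                    ix$retina, ix$rpe)
}

#' Run the full analysis pipeline on a cohort directory
#'
#' Reads the cohort manifest and metadata, computes per-eye biometry from
#' the OCT volumes, per-eye refraction from the pupil frames, per-eye IOP
#' from the tonometer readings and per-fish OKR summaries from the angle
#' traces, then fits the compound-symmetry mixed model per metric against
#' the wild-type reference and writes all tables as CSV. Missing inputs are
#' enumerated before any computation; the run is deterministic for a given
#' cohort.
#'
#' @param cohortDir directory created by [makeCohort()].
#' @param outDir output directory for result CSVs.
#' @param config a `PipelineConfig` (see [defaultPipelineConfig()]).
#' @return invisible list with `biometry`, `refraction`, `iop`, `okr`,
#'   `effects` (per metric/genotype: effect, SE, df, p, stars) and
#'   `size_match`.
#' @export
runPipeline <- function(cohortDir, outDir = file.path(cohortDir, "results"),
                        config = defaultPipelineConfig()) {
  manifest <- readManifest(cohortDir)
  meta <- utils::read.csv(file.path(cohortDir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  missing <- character(0)
  for (eyeId in names(manifest$files)) {
    rec <- manifest$files[[eyeId]]
    for (k in intersect(names(rec), c("oct", "pupil", "iop"))) {
      p <- file.path(cohortDir, rec[[k]])
      if (!file.exists(p) && !dir.exists(p)) missing <- c(missing, p)
    }
  }
  if (length(missing))
    stop("missing inputs:\n  ", paste(missing, collapse = "\n  "))

  indices <- .indicesFromConfig(config)
  calib <- defaultCalibration(config$refraction$gain,
                              config$refraction$offset)

  biom <- list(); refr <- list(); iop <- list()
  for (eyeId in names(manifest$files)) {
    rec <- manifest$files[[eyeId]]
    if (!is.null(rec$oct)) {
      vol <- readOctVolume(file.path(cohortDir, rec$oct))
      b <- as.data.frame(computeBiometry(vol, indices))
      b$eye_id <- eyeId
      biom[[eyeId]] <- b
    }
    if (!is.null(rec$pupil)) {
      fr <- sort(list.files(file.path(cohortDir, rec$pupil),
                            pattern = "\\.png$", full.names = TRUE))
      frames <- lapply(fr, function(p) png::readPNG(p) * 255)
      r <- measureRefraction(frames, calib)
      refr[[eyeId]] <- data.frame(eye_id = eyeId,
                                  mean_diopters = r@meanDiopters,
                                  sd_diopters = r@sdDiopters,
                                  n_measurements = r@nMeasurements,
                                  qc_flags = paste(r@qcFlags,
                                                   collapse = ";"))
    }
    if (!is.null(rec$iop)) {
      df <- utils::read.csv(file.path(cohortDir, rec$iop))
      a <- aggregateIop(df$reading, expectedN = config$iop$expected_n,
                        eyeId = eyeId)
      iop[[eyeId]] <- data.frame(eye_id = eyeId, mean_iop = a$mean_iop,
                                 n_used = a$n_used,
                                 qc_flags = paste(a$qc_flags,
                                                  collapse = ";"))
    }
  }
  okr <- list()
  for (fishId in names(manifest$okr)) {
    tr <- readAngleTraceCsv(file.path(cohortDir,
                                      manifest$okr[[fishId]]$file))
    res <- analyzeOkr(tr, etmWindow = config$okr$etm_window,
                      velocityThreshold = config$okr$saccade_threshold,
                      smoothWindow = config$okr$smooth_window,
                      minDuration = config$okr$min_segment,
                      r2Min = config$okr$r2_min)
    okr[[fishId]] <- data.frame(
      fish_id = fishId, genotype = manifest$okr[[fishId]]$genotype,
      gain_tn = res@gainTn, gain_nt = res@gainNt,
      mean_etm_per_15s = mean(res@etmPer15s),
      no_response = res@noResponse)
  }

  bind <- function(x) if (length(x)) do.call(rbind, unname(x)) else NULL
  biomDf <- bind(biom); refrDf <- bind(refr); iopDf <- bind(iop)
  okrDf <- bind(okr)

  long <- list()
  addMetrics <- function(df, cols) {
    if (is.null(df)) return()
    m <- merge(df, meta, by = "eye_id")
    for (cc in cols) {
      long[[length(long) + 1]] <<- data.frame(
        fish_id = m$fish_id, eye = m$eye, genotype = m$genotype,
        age_label = m$age_label, metric_name = cc, value = m[[cc]],
        body_length = m$body_length)
    }
  }
  addMetrics(biomDf, c("corneal_thickness", "acd", "lens_diameter", "vcd",
                       "retinal_thickness", "rpe_thickness",
                       "axial_length"))
  addMetrics(refrDf, "mean_diopters")
  addMetrics(iopDf, "mean_iop")
  longDf <- if (length(long)) do.call(rbind, long) else NULL

  effects <- NULL
  ref <- NULL
  genos <- unique(meta$genotype)
  refCand <- genos[startsWith(genos, config$stats$reference_prefix)]
  if (length(refCand) == 1 && length(genos) >= 2 && !is.null(longDf)) {
    ref <- refCand
    rows <- list()
    for (metric in unique(longDf$metric_name)) {
      sub <- longDf[longDf$metric_name == metric &
                      is.finite(longDf$value), ]
      if (length(unique(sub$genotype)) < 2) next
      fit <- fitCsMixed(sub, metric, reference = ref)
      for (g in names(effectSize(fit))) {
        rows[[length(rows) + 1]] <- data.frame(
          metric = metric, genotype = g, reference = ref,
          effect = effectSize(fit)[[g]], se = fit@se[[g]],
          df = fit@df[[g]], p = pValue(fit)[[g]],
          stars = pStars(pValue(fit)[[g]]))
      }
    }
    effects <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  sizeMatch <- if (!is.null(ref))
    sizeMatchFilter(meta, reference = ref,
                    tolerance = config$stats$size_tolerance) else NULL

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(outDir, name), row.names = FALSE)
  wr(biomDf, "biometry.csv"); wr(refrDf, "refraction.csv")
  wr(iopDf, "iop.csv"); wr(okrDf, "okr.csv"); wr(effects, "effects.csv")
  if (!is.null(sizeMatch)) wr(sizeMatch$report, "size_match.csv")

  invisible(list(biometry = biomDf, refraction = refrDf, iop = iopDf,
                 okr = okrDf, effects = effects, size_match = sizeMatch))
}
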