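#' Specify a synthetic cohort
#'
#' A cohort draws `nFishPerGenotype` fish (two eyes each) per preset.
#' Eye-level geometry is the preset mean plus a between-fish effect and a
#' between-eye effect; noise SDs are proportional to the age-matched
#' wild-type component means. The defaults (1% between fish, 0.5% between
#' eyes) reflect cohorts that are body-length matched to within 1% of the
#' wild-type mean, which bounds residual between-fish ocular size variation
#' at about the same relative scale. Body lengths are drawn from a common
#' distribution for all genotypes, so cohorts pass the 1% size-matching
#' rule by construction.
#'
#' @param presets character vector of [listEyePresets()] names (one
#'   genotype/age each); all should share one age.
#' @param nFishPerGenotype fish per genotype (default 10, i.e. 20 eyes).
#' @param fishCv between-fish coefficient of variation per component.
#' @param eyeCv between-eye coefficient of variation per component.
#' @param refractionFishSd,refractionEyeSd diopter noise SDs for the
#'   photorefraction stream.
#' @param iopSd tonometer reading SD, mmHg.
#' @param bodyLengthMean,bodyLengthSd body length distribution, mm.
#' @param seed integer seed; fully determines every generated file.
#' @return list of class `CohortSpec`.
#' @export
cohortSpec <- function(presets = c("wt_6mpf", "prss56_6mpf"),
                       nFishPerGenotype = 10, fishCv = 0.01, eyeCv = 0.005,
                       refractionFishSd = 1, refractionEyeSd = 0.5,
                       iopSd = 1.5, bodyLengthMean = 30, bodyLengthSd = 0.1,
                       seed = 1) {
  stopifnot(all(presets %in% listEyePresets()), nFishPerGenotype >= 1)
  structure(list(presets = presets, nFishPerGenotype = nFishPerGenotype,
                 fishCv = fishCv, eyeCv = eyeCv,
                 refractionFishSd = refractionFishSd,
                 refractionEyeSd = refractionEyeSd, iopSd = iopSd,
                 bodyLengthMean = bodyLengthMean,
                 bodyLengthSd = bodyLengthSd, seed = as.integer(seed)),
            class = "CohortSpec")
}

.presetAge <- function(preset) sub(".*_", "", preset)

# Draw the per-eye geometries for one genotype: preset mean + fish effect +
# eye effect, SDs proportional to the age-matched WT component means.
.drawGeometries <- function(preset, nFish, fishCv, eyeCv) {
  mu <- geometryValues(makeEyeGeometry(preset))
  wt <- geometryValues(makeEyeGeometry(paste0("wt_", .presetAge(preset))))
  sdFish <- pmax(fishCv * wt, 0.25)
  sdEye <- pmax(eyeCv * wt, 0.1)
  out <- vector("list", nFish * 2)
  k <- 0L
  for (i in seq_len(nFish)) {
    fishEff <- stats::rnorm(length(mu), 0, sdFish)
    for (e in 1:2) {
      v <- mu + fishEff + stats::rnorm(length(mu), 0, sdEye)
      v <- pmax(v, c(rep(1, 1), 0, rep(1, 6))[seq_along(v)])
      k <- k + 1L
      out[[k]] <- v
    }
  }
  out
}

#' Generate a synthetic multi-assay cohort on disk
#'
#' Writes, per eye/fish, the raw-data streams of the four assays (OCT
#' volumes as multi-page TIFF with a JSON sidecar, pupil frames as PNG,
#' eye-angle traces and tonometer readings as CSV), a cohort `metadata.csv`
#' and a `manifest.json` listing every file together with its ground-truth
#' generating parameters, so downstream analyses can be validated by round
#' trip.
#'
#' @param spec a [cohortSpec()].
#' @param outDir output directory (created if missing).
#' @param assays subset of `c("oct", "refraction", "okr", "iop")`.
#' @param renderConfig an [octRenderConfig()].
#' @param indices a [RefractiveIndexSet-class] used by the OCT forward
#'   model.
#' @param calibration a [RefractionCalibration-class] used as the forward
#'   slope model for pupil frames.
#' @param pupilFramesPerEye frames per eye for the photorefraction stream.
#' @param pupilNoiseSd intensity noise of pupil frames (a.u.).
#' @param okrDuration,okrNoiseSd OKR trace duration (s) and angle noise
#'   (deg).
#' @param iopN tonometer readings per eye.
#' @return the manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
makeCohort <- function(spec, outDir,
                       assays = c("oct", "refraction", "okr", "iop"),
                       renderConfig = octRenderConfig(),
                       indices = refractiveIndices(),
                       calibration = defaultCalibration(),
                       pupilFramesPerEye = 100, pupilNoiseSd = 2,
                       okrDuration = 60, okrNoiseSd = 0.5, iopN = 6) {
  stopifnot(inherits(spec, "CohortSpec"))
  assays <- match.arg(assays, several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  for (d in intersect(assays, c("oct", "pupil", "okr", "iop")))
    dir.create(file.path(outDir, sub("refraction", "pupil", d)),
               showWarnings = FALSE)
  if ("refraction" %in% assays)
    dir.create(file.path(outDir, "pupil"), showWarnings = FALSE)

  withSeed(spec$seed, {
    meta <- list(); eyes <- list()
    for (g in spec$presets) {
      geoms <- .drawGeometries(g, spec$nFishPerGenotype, spec$fishCv,
                               spec$eyeCv)
      ap <- assayPresets(g)
      bl <- stats::rnorm(spec$nFishPerGenotype, spec$bodyLengthMean,
                         spec$bodyLengthSd)
      k <- 0L
      for (i in seq_len(spec$nFishPerGenotype)) {
        fishId <- sprintf("%s_f%02d", g, i)
        refrFish <- stats::rnorm(1, 0, spec$refractionFishSd)
        okrVel <- ap$okr_velocity
        for (e in c("L", "R")) {
          k <- k + 1L
          eyeId <- paste0(fishId, "_", e)
          v <- geoms[[k]]
          trueD <- if (is.na(ap$refraction_d)) NA_real_ else
            ap$refraction_d + refrFish +
            stats::rnorm(1, 0, spec$refractionEyeSd)
          eyes[[eyeId]] <- list(
            eye_id = eyeId, fish_id = fishId, eye = e, genotype = g,
            body_length = bl[i], geometry = as.list(v),
            true_diopters = trueD, true_okr_velocity = okrVel,
            true_iop = ap$iop_mmhg)
          meta[[eyeId]] <- data.frame(
            eye_id = eyeId, fish_id = fishId, eye = e, genotype = g,
            age_label = .presetAge(g), body_length = bl[i],
            stringsAsFactors = FALSE)
        }
      }
    }

    manifest <- list(seed = spec$seed, assays = assays, files = list())
    for (eyeId in names(eyes)) {
      info <- eyes[[eyeId]]
      rec <- list(truth = info)
      if ("oct" %in% assays) {
        v <- unlist(info$geometry)
        geom <- eyeGeometry(v[["cornealThickness"]], v[["acd"]],
                            v[["lensDiameter"]], v[["vcd"]],
                            v[["retinalThickness"]], v[["rpeThickness"]],
                            v[["equatorialDiameterX"]],
                            v[["equatorialDiameterY"]])
        volSeed <- spec$seed + match(eyeId, names(eyes))
        vol <- renderOctVolume(geom, renderConfig, indices, seed = volSeed)
        p <- file.path(outDir, "oct", paste0(eyeId, ".tiff"))
        writeOctVolume(vol, p)
        rec$oct <- file.path("oct", paste0(eyeId, ".tiff"))
      }
      if ("refraction" %in% assays && !is.na(info$true_diopters)) {
        slope <- (info$true_diopters - calibration@offset) / calibration@gain
        dirp <- file.path(outDir, "pupil", eyeId)
        dir.create(dirp, showWarnings = FALSE)
        for (f in seq_len(pupilFramesPerEye)) {
          img <- renderPupilFrame(slope, noiseSd = pupilNoiseSd)
          png::writePNG(img / 255,
                        file.path(dirp, sprintf("f%03d.png", f)))
        }
        rec$pupil <- file.path("pupil", eyeId)
      }
      if ("iop" %in% assays) {
        readings <- synthIopReadings(info$true_iop, spec$iopSd, iopN)
        p <- file.path(outDir, "iop", paste0(eyeId, ".csv"))
        utils::write.csv(data.frame(eye_id = eyeId, reading = readings),
                         p, row.names = FALSE)
        rec$iop <- file.path("iop", paste0(eyeId, ".csv"))
      }
      manifest$files[[eyeId]] <- rec
    }

    if ("okr" %in% assays) {
      manifest$okr <- list()
      for (g in spec$presets) {
        ap <- assayPresets(g)
        for (i in seq_len(spec$nFishPerGenotype)) {
          fishId <- sprintf("%s_f%02d", g, i)
          vel <- ap$okr_velocity
          # resetting saccades of ~20 deg; slower tracking accumulates the
          # reset amplitude more slowly, hence fewer ETMs per interval
          tr <- synthOkrTrace(vel,
                              saccadeInterval = if (vel > 0) 20 / vel else 1,
                              saccadeAmplitude = 20,
                              duration = okrDuration,
                              noiseSd = okrNoiseSd)
          p <- file.path(outDir, "okr", paste0(fishId, ".csv"))
          writeAngleTraceCsv(tr, p)
          manifest$okr[[fishId]] <- list(
            file = file.path("okr", paste0(fishId, ".csv")),
            genotype = g, true_velocity = vel)
        }
      }
    }

    metaDf <- do.call(rbind, meta)
    utils::write.csv(metaDf, file.path(outDir, "metadata.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
  })
}

#' Read a cohort manifest
#'
#' @param dir cohort directory created by [makeCohort()].
#' @return manifest list.
#' @export
readManifest <- function(dir) {
  p <- file.path(dir, "manifest.json")
  if (!file.exists(p)) stop("no manifest.json in ", dir)
  jsonlite::read_json(p, simplifyVector = FALSE)
}

#' Write / read an eye-angle trace as CSV
#'
#' Columns: `time_s`, `angle_left_deg`, `angle_right_deg`; stimulus
#' parameters travel in comment header lines (`# key: value`).
#'
#' @param trace an [AngleTrace-class].
#' @param path CSV path.
#' @return `writeAngleTraceCsv` returns `path` invisibly;
#'   `readAngleTraceCsv` returns an [AngleTrace-class].
#' @export
writeAngleTraceCsv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# drum_velocity: ", trace@stimulus$drum_velocity),
    paste0("# spatial_frequency: ", trace@stimulus$spatial_frequency),
    paste0("# direction: ", trace@stimulus$direction),
    paste0("# sample_rate: ", trace@sampleRate)), con)
  utils::write.csv(data.frame(time_s = trace@time,
                              angle_left_deg = trace@angleLeft,
                              angle_right_deg = trace@angleRight),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeAngleTraceCsv
#' @export
readAngleTraceCsv <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(key, default) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(default)
    sub(paste0("^# ", key, ": *"), "", ln[1])
  }
  df <- utils::read.csv(path, comment.char = "#")
  angleTrace(df$time_s, df$angle_left_deg, df$angle_right_deg,
             as.numeric(getv("sample_rate", "60")),
             list(drum_velocity = as.numeric(getv("drum_velocity", "20")),
                  spatial_frequency =
                    as.numeric(getv("spatial_frequency", "0.15")),
                  direction = getv("direction", "cw")))
}
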