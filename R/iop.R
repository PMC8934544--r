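#' Synthesize rebound-tonometer readings
#'
#' @param trueIop true intraocular pressure, mmHg.
#' @param sd reading noise, mmHg (>= 0).
#' @param n number of readings (>= 1; the protocol takes six per eye).
#' @param seed integer seed.
#' @return numeric vector of `n` readings.
#' @export
synthIopReadings <- function(trueIop, sd = 1, n = 6, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (sd < 0) stop("sd must be >= 0")
  withSeed(seed, trueIop + stats::rnorm(n, 0, sd))
}

#' Aggregate tonometer readings into a per-eye IOP
#'
#' Plain averaging of the (typically six) readings per eye; non-finite or
#' non-positive readings are dropped with a qc flag, and a flag is raised
#' when the retained count differs from the expected protocol count. No
#' outlier rejection is applied beyond the validity filter.
#'
#' @param readings numeric vector of readings, mmHg.
#' @param expectedN expected number of readings per eye (protocol: 6).
#' @param eyeId optional eye identifier carried through to the result.
#' @return list of class `IopRecord` with `eye_id`, `readings`, `mean_iop`,
#'   `n_used` and `qc_flags`.
#' @examples
#' aggregateIop(c(8, 9, 10, 11, 12, 10))$mean_iop  # 10
#' @export
aggregateIop <- function(readings, expectedN = 6, eyeId = NA_character_) {
  if (!length(readings)) stop("no readings supplied")
  qc <- character(0)
  valid <- is.finite(readings) & readings > 0
  if (any(!valid))
    qc <- c(qc, paste0("invalid_readings:", sum(!valid)))
  kept <- readings[valid]
  if (!length(kept)) stop("no valid readings to aggregate")
  if (length(kept) != expectedN)
    qc <- c(qc, paste0("n_used_not_", expectedN))
  structure(list(eye_id = eyeId, readings = readings,
                 mean_iop = mean(kept), n_used = length(kept),
                 qc_flags = qc),
            class = "IopRecord")
}

#' @export
print.IopRecord <- function(x, ...) {
  cat(sprintf("IopRecord%s: %.2f mmHg (n = %d/%d readings)%s\n",
              if (is.na(x$eye_id)) "" else paste0(" [", x$eye_id, "]"),
              x$mean_iop, x$n_used, length(x$readings),
              if (length(x$qc_flags))
                paste0("  qc: ", paste(x$qc_flags, collapse = ";")) else ""))
  invisible(x)
}

#' Read per-eye tonometer readings from CSV
#'
#' Expects columns `eye_id` and `reading` (one row per reading).
#'
#' @param path CSV path.
#' @param expectedN expected readings per eye.
#' @return data.frame with one row per eye: `eye_id`, `mean_iop`, `n_used`,
#'   `qc_flags`.
#' @export
readIopCsv <- function(path, expectedN = 6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("eye_id", "reading") %in% names(df)))
  out <- lapply(split(df$reading, df$eye_id), aggregateIop,
                expectedN = expectedN)
  data.frame(eye_id = names(out),
             mean_iop = vapply(out, `[[`, numeric(1), "mean_iop"),
             n_used = vapply(out, `[[`, integer(1), "n_used"),
             qc_flags = vapply(out, function(r)
               paste(r$qc_flags, collapse = ";"), character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
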