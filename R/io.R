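# Plain-text interchange formats.  Everything is inspectable delimited text:
# trial logs and measure tables as CSV with a header, EEG as CSV behind a
# one-line `# fs=... channel=...` header, configs and ground-truth sidecars
# as JSON.  Numeric columns are written with %.17g so doubles round-trip
# exactly.

.required_log_cols <- c("subject", "session", "task", "condition",
                        "trial_index", "level", "unit", "response_correct",
                        "track_id", "seed")

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a trial log
#'
#' One row per forced-choice trial with the standard columns
#' `subject, session, task, condition, trial_index, level, unit,
#' response_correct, track_id, seed`; any extra annotation columns are
#' preserved.  Comma-separated with a header line.
#'
#' @param records Data.frame containing at least the required columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(records, path) {
  missing <- setdiff(.required_log_cols, names(records))
  if (length(missing)) {
    stop("trial log lacks required column(s): ", paste(missing, collapse = ", "))
  }
  out <- records
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]])) {
      out[[nm]] <- .fmt_num(out[[nm]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial log
#'
#' Validates the header and parses levels as decimal numbers; malformed
#' rows are rejected with their line number rather than silently coerced.
#'
#' @param path File written by [write_trial_log()].
#' @return A data.frame with `level` numeric, `response_correct` logical,
#'   and any extra columns untouched.
#' @export
read_trial_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  missing <- setdiff(.required_log_cols, names(d))
  if (length(missing)) {
    stop("trial log is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (nm in c("trial_index", "level", "seed", "session")) {
    v <- suppressWarnings(as.numeric(d[[nm]]))
    bad <- which(is.na(v) & d[[nm]] != "NA")
    if (length(bad)) {
      stop(sprintf("malformed value in column '%s' at line %d: '%s'",
                   nm, bad[1] + 1L, d[[nm]][bad[1]]))
    }
    d[[nm]] <- v
  }
  rc <- d$response_correct
  ok <- rc %in% c("TRUE", "FALSE", "true", "false", "0", "1")
  if (any(!ok)) {
    stop(sprintf("malformed value in column 'response_correct' at line %d: '%s'",
                 which(!ok)[1] + 1L, rc[which(!ok)[1]]))
  }
  d$response_correct <- rc %in% c("TRUE", "true", "1")
  if (!all(d$unit %in% c("Hz", "arcsec", "logMAR", "px"))) {
    stop("column 'unit' contains values outside {Hz, arcsec, logMAR, px}")
  }
  d
}

#' Write an EEG recording as delimited text
#'
#' Format: a single header line `# fs=<Hz> channel=<label> epoch=<s>`
#' followed by a CSV table `sample_index,value_uV,trigger,condition`, where
#' `trigger` is 1 on epoch-start samples and `condition` carries the eye
#' condition label on trigger rows (empty elsewhere).
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.17g channel=%s epoch=%.17g",
                     recording$sampling_rate, recording$channel,
                     recording$epoch_duration), con)
  n <- length(recording$samples)
  trig <- integer(n)
  cond <- character(n)
  trig[recording$trigger_indices] <- 1L
  cond[recording$trigger_indices] <- recording$condition_labels
  writeLines("sample_index,value_uV,trigger,condition", con)
  writeLines(paste(seq_len(n), .fmt_num(recording$samples), trig, cond,
                   sep = ","), con)
  invisible(path)
}

#' Read an EEG recording from delimited text
#'
#' @param path File written by [write_eeg()].
#' @param expected_fs If given, the header's sampling rate must match it
#'   exactly.
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, expected_fs = NULL) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# ")) {
    stop("EEG file lacks the '# fs=... channel=...' header line")
  }
  fields <- strsplit(sub("^# ", "", header), " ")[[1]]
  kv <- strsplit(fields, "=")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  fs <- as.numeric(vals[["fs"]])
  if (!is.null(expected_fs) && fs != expected_fs) {
    stop(sprintf("sampling rate mismatch: file declares fs=%g, expected %g",
                 fs, expected_fs))
  }
  d <- utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE,
                       colClasses = c("integer", "character", "integer",
                                      "character"))
  v <- suppressWarnings(as.numeric(d$value_uV))
  bad <- which(is.na(v))
  if (length(bad)) {
    stop(sprintf("malformed value_uV at line %d", bad[1] + 2L))
  }
  trig_idx <- which(d$trigger == 1L)
  eeg_recording(v, fs, trig_idx, d$condition[trig_idx],
                epoch_duration = as.numeric(vals[["epoch"]]),
                channel = vals[["channel"]])
}

#' Write a ground-truth sidecar
#'
#' JSON record of the generating parameters placed next to every synthetic
#' dataset, so recovery tests can compare estimates to the construction.
#'
#' @param truth A list (or S3 object coercible to one).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
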