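# Trial and manifest I/O ----------------------------------------------------
#
# CSV contract for a trial: header row, comma separated, columns
#   time (optional, seconds), fz_left, fz_right   (vertical GRF in N)
# Manifest: athlete_id, session, involved_side, path [, mass_kg]

#' Construct a raw dual-plate trial
#'
#' A trial holds one synchronized pair of vertical ground reaction force
#' (vGRF) channels, one per limb, in newtons, plus metadata.  Channels
#' must be equal length, finite, and long enough to contain at least one
#' second of quiet standing followed by the movement (>= 2 s in total).
#'
#' @param trial_id,athlete_id character identifiers.
#' @param session session code, `"T0"` (baseline) or `"T1"` (follow-up).
#' @param fs sampling rate in Hz (> 0).
#' @param f_left,f_right per-limb vGRF series in N, equal length.
#' @param involved_side which limb is the involved one, `"left"` or
#'   `"right"`.
#' @param mass_kg optional body mass in kg (`NA` if unknown; the pipeline
#'   derives mass from body weight when absent).
#' @return an object of class `cmj_trial`.
#' @export
raw_trial <- function(trial_id, athlete_id, session, fs, f_left, f_right,
                      involved_side, mass_kg = NA_real_) {
  session <- match.arg(session, c("T0", "T1"))
  involved_side <- match.arg(involved_side, c("left", "right"))
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    cmj_stop("`fs` must be a single positive number", "cmj_format_error")
  }
  f_left <- as.numeric(f_left)
  f_right <- as.numeric(f_right)
  if (length(f_left) != length(f_right)) {
    cmj_stop("left and right force channels differ in length", "cmj_format_error")
  }
  if (anyNA(f_left) || anyNA(f_right) ||
      !all(is.finite(f_left)) || !all(is.finite(f_right))) {
    cmj_stop("force channels contain non-finite values", "cmj_data_error")
  }
  if (length(f_left) < 2) {
    cmj_stop("force channels need at least 2 samples", "cmj_data_error")
  }
  structure(
    list(
      trial_id = as.character(trial_id),
      athlete_id = as.character(athlete_id),
      session = session,
      fs = as.numeric(fs),
      f_left = f_left,
      f_right = f_right,
      involved_side = involved_side,
      mass_kg = as.numeric(mass_kg)
    ),
    class = "cmj_trial"
  )
}

#' @export
print.cmj_trial <- function(x, ...) {
  cat(sprintf(
    "<cmj_trial %s> athlete %s, session %s, %d samples @ %g Hz, involved: %s\n",
    x$trial_id, x$athlete_id, x$session, length(x$f_left), x$fs,
    x$involved_side
  ))
  invisible(x)
}

#' Total vGRF of a trial (left + right), in N
#' @param trial a `cmj_trial`.
#' @return numeric vector.
#' @export
total_force <- function(trial) trial$f_left + trial$f_right

#' Read one trial from CSV
#'
#' Expects a header row with columns `fz_left` and `fz_right` (N) and an
#' optional `time` column (seconds).  If a time column is present the
#' sampling rate is inferred from the median sample spacing and must
#' agree with any declared `fs` within 1%.
#'
#' @param path CSV file path.
#' @param trial_id,athlete_id,session,involved_side,mass_kg trial
#'   metadata (see [raw_trial()]).
#' @param fs declared sampling rate in Hz; may be `NULL` when the file
#'   carries a time column.
#' @return a `cmj_trial`.
#' @export
read_trial_csv <- function(path, trial_id, athlete_id, session,
                           involved_side, fs = NULL, mass_kg = NA_real_) {
  if (!file.exists(path)) {
    cmj_stop(sprintf("trial file not found: %s", path), "cmj_format_error")
  }
  df <- read.csv(path, check.names = FALSE)
  for (col in c("fz_left", "fz_right")) {
    if (!col %in% names(df)) {
      cmj_stop(sprintf("missing column `%s` in %s", col, path),
               "cmj_format_error")
    }
  }
  if ("time" %in% names(df)) {
    tcol <- df$time
    dt <- diff(tcol)
    if (anyNA(tcol) || any(dt <= 0)) {
      cmj_stop("time column is not strictly increasing", "cmj_format_error")
    }
    fs_inferred <- 1 / median(dt)
    if (!is.null(fs) && abs(fs_inferred - fs) / fs > 0.01) {
      cmj_stop(sprintf(
        "declared fs = %g Hz disagrees with time column (inferred %g Hz) by more than 1%%",
        fs, fs_inferred
      ), "cmj_format_error")
    }
    fs <- fs %||% fs_inferred
  } else if (is.null(fs)) {
    cmj_stop("no time column and no declared sampling rate", "cmj_format_error")
  }
  if (anyNA(df$fz_left) || anyNA(df$fz_right)) {
    cmj_stop("NaN/NA force values in trial file", "cmj_data_error")
  }
  raw_trial(trial_id, athlete_id, session, fs, df$fz_left, df$fz_right,
            involved_side, mass_kg)
}

#' Write a trial to CSV
#'
#' Writes `time,fz_left,fz_right` with enough digits that a
#' read-write-read round trip reproduces the force channels
#' bit-identically.
#'
#' @param trial a `cmj_trial`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  n <- length(trial$f_left)
  tt <- (seq_len(n) - 1) / trial$fs
  lines <- c(
    "time,fz_left,fz_right",
    paste(fmt_full(tt), fmt_full(trial$f_left), fmt_full(trial$f_right),
          sep = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' The manifest maps trial files to athlete, session and involved limb:
#' columns `athlete_id, session, involved_side, path` and optionally
#' `mass_kg`.  The involved side must be constant within an athlete.
#' Athletes with trials at only one session are retained but flagged
#' `paired = FALSE` and are excluded from paired contrasts downstream.
#'
#' @param path manifest CSV path.
#' @param base_dir directory against which relative trial paths are
#'   resolved; defaults to the manifest's directory.
#' @return a data frame of class `cmj_manifest` with an added logical
#'   column `paired`.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) {
    cmj_stop(sprintf("manifest not found: %s", path), "cmj_format_error")
  }
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("athlete_id", "session", "involved_side", "path")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    cmj_stop(paste("manifest missing columns:", paste(miss, collapse = ", ")),
             "cmj_format_error")
  }
  if (!"mass_kg" %in% names(df)) df$mass_kg <- NA_real_
  if (!all(df$session %in% c("T0", "T1"))) {
    cmj_stop("manifest sessions must be T0 or T1", "cmj_format_error")
  }
  if (!all(df$involved_side %in% c("left", "right"))) {
    cmj_stop("involved_side must be left or right", "cmj_format_error")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(base_dir, df$path[rel])
  validate_manifest(df)
}

#' Validate an in-memory manifest data frame
#' @param df data frame with manifest columns.
#' @return the validated `cmj_manifest`.
#' @export
validate_manifest <- function(df) {
  by_ath <- split(df$involved_side, df$athlete_id)
  bad <- names(by_ath)[vapply(by_ath, function(s) length(unique(s)) > 1, logical(1))]
  if (length(bad)) {
    cmj_stop(paste(
      "involved_side differs across rows for athlete(s):",
      paste(bad, collapse = ", ")
    ), "cmj_consistency_error")
  }
  sess <- split(df$session, df$athlete_id)
  paired_ath <- names(sess)[vapply(
    sess, function(s) all(c("T0", "T1") %in% s), logical(1)
  )]
  df$paired <- df$athlete_id %in% paired_ath
  class(df) <- c("cmj_manifest", "data.frame")
  df
}
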