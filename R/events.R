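# Event detection -----------------------------------------------------------
#
# Body weight from a 1 s quiet-standing window; movement onset by two
# methods (threshold crossing at BW - 5SD, and a backward search that
# captures a "preload" rise above BW + 5SD); take-off when the total
# force falls below 20 N; trial-level QC flags.

TAKEOFF_THRESHOLD_N <- 20

#' Estimate body weight from quiet standing
#'
#' Body weight (BW) is the mean total vGRF over a 1 s quiet-standing
#' window, with its standard deviation retained for the onset
#' thresholds.  The default policy takes the first second of the
#' recording; if that window is not stationary (SD < `sd_max` N and
#' range < `range_max` N) the window slides forward in 0.1 s steps and
#' the minimum-SD window ending before gross movement is used, with
#' `stationary = FALSE` recorded for QC.
#'
#' @param trial a `cmj_trial`.
#' @param sd_max stationarity limit on window SD, N.
#' @param range_max stationarity limit on window range, N.
#' @return a `cmj_bodyweight` list: `bw` (N), `sd` (N), `window`
#'   (first/last sample index), `stationary` (logical).
#' @export
estimate_body_weight <- function(trial, sd_max = 10, range_max = 50) {
  f <- total_force(trial)
  w <- as.integer(round(trial$fs))
  n <- length(f)
  if (n < w) cmj_stop("trial shorter than 1 s", "cmj_data_error")

  # bound the search: windows must end before gross movement, taken as
  # the first drop below 75% of the initial-second mean
  init_mean <- mean(f[seq_len(w)])
  drop <- which(f < 0.75 * init_mean)
  limit <- if (length(drop)) drop[1] - 1L else n

  w <- as.integer(w)
  starts <- seq.int(1L, max(1L, min(limit, n) - w + 1L),
                    by = max(1L, as.integer(round(0.1 * trial$fs))))
  best <- NULL
  for (s in starts) {
    idx <- s:(s + w - 1L)
    wsd <- sd(f[idx])
    wrange <- diff(range(f[idx]))
    ok <- wsd < sd_max && wrange < range_max
    if (is.null(best) || wsd < best$sd) {
      best <- list(bw = mean(f[idx]), sd = wsd, window = c(s, s + w - 1L),
                   stationary = ok)
    }
    if (ok) {
      best <- list(bw = mean(f[idx]), sd = wsd, window = c(s, s + w - 1L),
                   stationary = TRUE)
      break
    }
  }
  structure(best, class = "cmj_bodyweight")
}

#' Movement onset, method 1 (threshold crossing)
#'
#' The first sample, after the body-weight window, at which the total
#' vGRF drops below `bw - 5 * sd`.  This marks the initial downward
#' displacement of the centre of mass and is the start point used for
#' waveform time normalization.
#'
#' @param trial a `cmj_trial`.
#' @param bw a `cmj_bodyweight`.
#' @return sample index (integer).
#' @export
detect_onset_threshold <- function(trial, bw) {
  f <- total_force(trial)
  from <- bw$window[2] + 1L
  thr <- bw$bw - 5 * bw$sd
  hit <- which(f[from:length(f)] < thr)
  if (!length(hit)) {
    cmj_stop("force never crosses the onset threshold (no movement)",
             "cmj_no_movement")
  }
  from + hit[1] - 1L
}

#' Movement onset, method 2 (backward preload search)
#'
#' Starting from the method-1 onset, search the preceding 100 ms for any
#' exceedance of the inverse threshold `bw + 5 * sd`; if found, step
#' back to the earliest such exceedance and repeat.  The returned index
#' is the last sample inside the band `[bw - 5 sd, bw + 5 sd]` before
#' the excursion chain first departed it, which captures a small rise of
#' the centre of mass ("preload") preceding the unweighting drop.  With
#' no exceedance within the lookback, method 1's index is returned
#' unchanged.  This is the start point for the impulse-momentum
#' integration, where a stationary (zero-velocity) start is assumed.
#'
#' @param trial a `cmj_trial`.
#' @param bw a `cmj_bodyweight`.
#' @param onset_m1 index from [detect_onset_threshold()].
#' @param lookback_s backward search horizon in seconds (default 0.1).
#' @param rule termination reading: `"first_departure"` (default)
#'   returns the last in-band sample before the excursion first left the
#'   band; `"band_reentry"` returns the last in-band sample immediately
#'   preceding the final downward departure into onset.
#' @return sample index (integer), always `<= onset_m1`.
#' @export
detect_onset_backtrack <- function(trial, bw, onset_m1,
                                   lookback_s = 0.1,
                                   rule = c("first_departure", "band_reentry")) {
  rule <- match.arg(rule)
  f <- total_force(trial)
  lb <- max(1L, round(lookback_s * trial$fs))
  upper <- bw$bw + 5 * bw$sd
  lower <- bw$bw - 5 * bw$sd

  cur <- onset_m1
  first_exceed <- NA_integer_
  repeat {
    lo <- max(1L, cur - lb)
    if (lo >= cur) break
    win <- lo:(cur - 1L)
    ex <- win[f[win] > upper]
    if (!length(ex)) break
    first_exceed <- ex[1]
    cur <- ex[1]
  }
  if (is.na(first_exceed)) return(onset_m1)

  if (rule == "first_departure") {
    before <- seq_len(first_exceed - 1L)
  } else {
    before <- seq_len(onset_m1 - 1L)
  }
  inband <- before[f[before] >= lower & f[before] <= upper]
  if (!length(inband)) return(max(1L, first_exceed - 1L))
  tail(inband, 1L)
}

#' Take-off detection
#'
#' Take-off is the first sample after the propulsion peak at which the
#' total vGRF decreases below 20 N.
#'
#' @param trial a `cmj_trial`.
#' @param onset movement-onset sample index.
#' @return sample index (integer).
#' @export
detect_takeoff <- function(trial, onset) {
  f <- total_force(trial)
  n <- length(f)
  peak <- onset - 1L + which.max(f[onset:n])
  if (peak >= n) cmj_stop("no samples after the propulsion peak", "cmj_no_takeoff")
  hit <- which(f[(peak + 1L):n] < TAKEOFF_THRESHOLD_N)
  if (!length(hit)) {
    cmj_stop("force never drops below 20 N after the peak (no take-off)",
             "cmj_no_takeoff")
  }
  peak + hit[1]
}

#' Trial quality-control flags
#'
#' Flags trials for exclusion:
#' \describe{
#'   \item{`no_stationary_baseline`}{no qualifying 1 s quiet-standing
#'     window was found (window SD/range limits violated everywhere).}
#'   \item{`total_unweighting`}{minimum total force between onset and
#'     the propulsion peak fell below 20 N.}
#'   \item{`no_takeoff`}{take-off could not be detected.}
#' }
#' Flagged trials are excluded from all downstream analysis.
#'
#' @param trial a `cmj_trial`.
#' @param bw a `cmj_bodyweight`.
#' @param events a `cmj_events` (possibly with `NA` fields).
#' @return character vector of flags (possibly empty).
#' @export
qc_trial <- function(trial, bw, events) {
  flags <- character(0)
  if (!isTRUE(bw$stationary)) flags <- c(flags, "no_stationary_baseline")
  if (is.na(events$takeoff)) {
    flags <- c(flags, "no_takeoff")
  } else if (!is.na(events$onset_m1)) {
    f <- total_force(trial)
    peak <- events$onset_m1 - 1L +
      which.max(f[events$onset_m1:length(f)])
    if (peak > events$onset_m1 &&
        min(f[events$onset_m1:peak]) < TAKEOFF_THRESHOLD_N) {
      flags <- c(flags, "total_unweighting")
    }
  }
  flags
}

#' Detect all trial events
#'
#' Convenience wrapper running body-weight estimation, both onset
#' methods, take-off detection and QC.  Detection failures are recorded
#' as `NA` indices plus QC flags rather than raised, so that cohort
#' processing can skip bad trials gracefully.
#'
#' @param trial a `cmj_trial`.
#' @param onset_rule passed to [detect_onset_backtrack()].
#' @return a `cmj_events` list: `bw` (the `cmj_bodyweight`), `onset_m1`,
#'   `onset_m2`, `takeoff` (sample indices or `NA`), `qc` (flags).
#' @export
detect_events <- function(trial, onset_rule = "first_departure") {
  bw <- estimate_body_weight(trial)
  onset_m1 <- tryCatch(detect_onset_threshold(trial, bw),
                       cmj_error = function(e) NA_integer_)
  onset_m2 <- if (is.na(onset_m1)) NA_integer_ else {
    detect_onset_backtrack(trial, bw, onset_m1, rule = onset_rule)
  }
  takeoff <- if (is.na(onset_m1)) NA_integer_ else {
    tryCatch(detect_takeoff(trial, onset_m1),
             cmj_error = function(e) NA_integer_)
  }
  ev <- structure(
    list(bw = bw, onset_m1 = onset_m1, onset_m2 = onset_m2,
         takeoff = takeoff, qc = character(0)),
    class = "cmj_events"
  )
  ev$qc <- qc_trial(trial, bw, ev)
  if (is.na(onset_m1)) ev$qc <- union(ev$qc, "no_movement")
  ev
}

#' @export
print.cmj_events <- function(x, ...) {
  cat(sprintf(
    "<cmj_events> bw = %.1f N (sd %.2f), onset m1/m2 = %s/%s, take-off = %s%s\n",
    x$bw$bw, x$bw$sd, x$onset_m1, x$onset_m2, x$takeoff,
    if (length(x$qc)) paste0(", QC: ", paste(x$qc, collapse = ",")) else ""
  ))
  invisible(x)
}
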