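# Cohort analysis pipeline ---------------------------------------------------
#
# Per-trial processing -> best-trial selection per (athlete, session)
# -> discrete comparison table + four SPM waveform contrasts.  Method-2
# onset drives the kinetic/asymmetry metrics (stationary-start
# assumption of the impulse-momentum calculation); method-1 onset
# anchors the time-normalized waveforms so all athletes share the same
# start definition.

#' Analyze one trial end to end
#'
#' Runs event detection, QC, impulse-momentum kinetics, phase
#' segmentation, all discrete metrics and both limbs' normalized
#' waveforms.  Trials failing QC (or where segmentation fails) return
#' with the failure flags and `NA` metrics rather than erroring, so
#' cohort processing can exclude them.
#'
#' @param trial a `cmj_trial`.
#' @param onset_rule backtracking rule, see [detect_onset_backtrack()].
#' @param net_waveform passed to [time_normalize()].
#' @return a `cmj_trial_result` list: identifiers, `qc`, `events`,
#'   `metrics` (one-row data frame), `waveforms` (involved/uninvolved,
#'   101 nodes each or `NULL`).
#' @export
analyze_trial <- function(trial, onset_rule = "first_departure",
                          net_waveform = FALSE) {
  events <- detect_events(trial, onset_rule = onset_rule)
  out <- list(
    trial_id = trial$trial_id, athlete_id = trial$athlete_id,
    session = trial$session, involved_side = trial$involved_side,
    qc = events$qc, events = events, metrics = empty_metrics_row(trial),
    waveforms = NULL
  )
  class(out) <- "cmj_trial_result"
  if (length(events$qc)) return(out)

  if (!is.na(trial$mass_kg) && is.finite(trial$mass_kg)) {
    m_derived <- events$bw$bw / GRAVITY
    if (abs(m_derived - trial$mass_kg) / trial$mass_kg > 0.02) {
      warning(sprintf(
        "trial %s: manifest mass %.1f kg disagrees with derived %.1f kg by > 2%%",
        trial$trial_id, trial$mass_kg, m_derived
      ))
    }
  }

  kin <- integrate_kinematics(trial, events$bw, events$onset_m2)
  phases <- tryCatch(segment_phases(kin, events), cmj_error = function(e) e)
  if (inherits(phases, "cmj_error")) {
    out$qc <- union(out$qc, class(phases)[1])
    return(out)
  }

  met <- out$metrics
  met$jump_height <- jump_height(kin, events)
  met$contraction_time <- contraction_time(events, trial$fs)
  met$rsi_mod <- rsi_mod(met$jump_height, met$contraction_time)
  for (limb in c("involved", "uninvolved")) {
    for (phase in c("unweighting", "braking", "propulsion")) {
      met[[paste0("imp_", phase, "_", limb)]] <-
        phase_impulse(trial, events$bw, phases, limb, phase)
    }
    met[[paste0("peak_force_", limb)]] <-
      peak_force(trial, events$bw, events, limb)
  }
  met$f_total <- f_total(met$peak_force_involved, met$peak_force_uninvolved)
  met$ai_peak_force <-
    asymmetry_index(met$peak_force_uninvolved, met$peak_force_involved)
  for (phase in c("unweighting", "braking", "propulsion")) {
    met[[paste0("ai_imp_", phase)]] <- asymmetry_index(
      met[[paste0("imp_", phase, "_uninvolved")]],
      met[[paste0("imp_", phase, "_involved")]]
    )
  }
  out$metrics <- met
  out$phases <- phases
  out$waveforms <- list(
    involved = time_normalize(trial, events, "involved", net = net_waveform),
    uninvolved = time_normalize(trial, events, "uninvolved", net = net_waveform)
  )
  out
}

#' @noRd
empty_metrics_row <- function(trial) {
  cols <- c(
    "jump_height", "contraction_time", "rsi_mod", "f_total",
    paste0("imp_", rep(c("unweighting", "braking", "propulsion"), 2), "_",
           rep(c("involved", "uninvolved"), each = 3)),
    "peak_force_involved", "peak_force_uninvolved",
    "ai_peak_force", paste0("ai_imp_", c("unweighting", "braking", "propulsion"))
  )
  row <- as.data.frame(as.list(setNames(rep(NA_real_, length(cols)), cols)))
  cbind(data.frame(trial_id = trial$trial_id, athlete_id = trial$athlete_id,
                   session = trial$session, stringsAsFactors = FALSE),
        row)
}

#' Analyze a cohort of trials
#'
#' Accepts a manifest (path, `cmj_manifest` data frame) or an in-memory
#' simulated cohort from [simulate_cohort()].  Per (athlete, session)
#' the QC-passing trial with the greatest jump height is selected; the
#' discrete comparison table and the four SPM waveform contrasts are
#' computed over athletes with valid best trials at both sessions.
#'
#' @param x manifest path, `cmj_manifest`, or `cmj_sim_cohort`.
#' @param alpha significance level.
#' @param spm_method `"rft"` or `"perm"`.
#' @param out_dir optional directory: writes the report bundle (metric
#'   tables as CSV, SPM results as JSON, figures, QC log).
#' @param seed RNG seed for permutation SPM.
#' @param min_pairs minimum paired athletes required (default 3).
#' @param onset_rule backtracking rule for method-2 onset.
#' @return a `cmj_cohort_analysis` list: `metrics` (best-trial wide data
#'   frame, one row per athlete-session), `waveforms` (nested matrices),
#'   `comparisons` (see [comparison_matrix()]), `qc` (per-trial flag
#'   table), `n_pairs`.
#' @export
analyze_cohort <- function(x, alpha = 0.05, spm_method = "rft",
                           out_dir = NULL, seed = NULL, min_pairs = 3,
                           onset_rule = "first_departure") {
  trials <- cohort_trials(x)
  results <- lapply(trials, analyze_trial, onset_rule = onset_rule)

  qc <- do.call(rbind, lapply(results, function(r) {
    data.frame(trial_id = r$trial_id, athlete_id = r$athlete_id,
               session = r$session,
               qc = paste(r$qc, collapse = ";"),
               bw = r$events$bw$bw, bw_sd = r$events$bw$sd,
               onset_m1 = r$events$onset_m1, onset_m2 = r$events$onset_m2,
               takeoff = r$events$takeoff, stringsAsFactors = FALSE)
  }))

  key <- paste(vapply(results, `[[`, "", "athlete_id"),
               vapply(results, `[[`, "", "session"), sep = "|")
  best <- list()
  for (k in unique(key)) {
    grp <- results[key == k]
    sel <- tryCatch(select_best_trial(grp), cmj_error = function(e) NULL)
    if (!is.null(sel)) best[[k]] <- sel
  }
  if (!length(best)) cmj_stop("no valid trials in cohort", "cmj_data_error")

  metrics <- do.call(rbind, lapply(best, `[[`, "metrics"))
  rownames(metrics) <- NULL

  waveforms <- list(involved = list(), uninvolved = list())
  for (session in c("T0", "T1")) {
    sel <- Filter(function(r) r$session == session, best)
    ids <- vapply(sel, `[[`, "", "athlete_id")
    for (limb in c("involved", "uninvolved")) {
      mat <- do.call(rbind, lapply(sel, function(r) r$waveforms[[limb]]))
      if (!is.null(mat)) rownames(mat) <- ids
      waveforms[[limb]][[session]] <- mat
    }
  }

  cohort <- list(metrics = metrics, waveforms = waveforms)
  paired_n <- length(intersect(metrics$athlete_id[metrics$session == "T0"],
                               metrics$athlete_id[metrics$session == "T1"]))
  dropped <- setdiff(unique(metrics$athlete_id),
                     intersect(metrics$athlete_id[metrics$session == "T0"],
                               metrics$athlete_id[metrics$session == "T1"]))
  if (length(dropped)) {
    warning(sprintf("dropping %d unpaired athlete(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  if (paired_n < min_pairs) {
    cmj_stop(sprintf("insufficient paired athletes (%d < %d)",
                     paired_n, min_pairs), "cmj_data_error")
  }
  comparisons <- comparison_matrix(cohort, alpha = alpha,
                                   spm_method = spm_method, seed = seed)
  res <- structure(
    list(metrics = metrics, waveforms = waveforms,
         comparisons = comparisons, qc = qc, n_pairs = paired_n,
         alpha = alpha, spm_method = spm_method),
    class = "cmj_cohort_analysis"
  )
  if (!is.null(out_dir)) write_cohort_report(res, out_dir)
  res
}

#' Materialize trials from any accepted cohort representation
#' @noRd
cohort_trials <- function(x) {
  if (inherits(x, "cmj_sim_cohort")) return(x$trials)
  if (is.character(x) && length(x) == 1) x <- read_manifest(x)
  if (inherits(x, "cmj_manifest") || is.data.frame(x)) {
    x <- validate_manifest(as.data.frame(x))
    trials <- list()
    for (i in seq_len(nrow(x))) {
      id <- sub("\\.csv$", "", basename(x$path[i]))
      trials[[id]] <- read_trial_csv(
        x$path[i], trial_id = id, athlete_id = x$athlete_id[i],
        session = x$session[i], involved_side = x$involved_side[i],
        mass_kg = x$mass_kg[i] %||% NA_real_
      )
    }
    return(trials)
  }
  cmj_stop("unsupported cohort input", "cmj_format_error")
}

#' @export
print.cmj_cohort_analysis <- function(x, ...) {
  cat(sprintf("<cmj_cohort_analysis> %d paired athletes, %d best trials, alpha = %g (%s SPM)\n",
              x$n_pairs, nrow(x$metrics), x$alpha, x$spm_method))
  sig <- x$comparisons$discrete
  sig <- sig[is.finite(sig$p) & sig$p < x$alpha, c("metric", "contrast", "p")]
  if (nrow(sig)) {
    cat("significant discrete contrasts:\n")
    print(sig, row.names = FALSE)
  } else cat("no significant discrete contrasts\n")
  invisible(x)
}
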