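# Discrete-metric group comparisons -----------------------------------------
#
# Paired comparisons gated by a Shapiro-Wilk normality test on the
# paired differences: paired t when normality is not rejected at 0.05,
# Wilcoxon signed-rank otherwise (Pratt handling of zero differences).
# No multiple-testing correction is applied.

#' Normality gate on paired differences
#'
#' Shapiro-Wilk test of the paired differences; `normal` is `TRUE` when
#' the test does not reject at 0.05.
#'
#' @param diffs numeric vector of paired differences (3 <= n <= 5000).
#' @return list with `normal` (logical) and `p`.
#' @export
normality_gate <- function(diffs) {
  diffs <- diffs[is.finite(diffs)]
  if (length(diffs) < 3 || length(diffs) > 5000) {
    cmj_stop("Shapiro-Wilk requires 3 <= n <= 5000", "cmj_data_error")
  }
  if (sd(diffs) == 0) return(list(normal = FALSE, p = NA_real_))
  p <- shapiro.test(diffs)$p.value
  list(normal = p >= 0.05, p = p)
}

#' Wilcoxon signed-rank with Pratt zero handling
#'
#' Zero differences are ranked together with the rest (by |d|) and then
#' dropped from the statistic; normal approximation with continuity
#' correction and tie correction.  Used when zeros are present; exact
#' signed-rank (via [stats::wilcox.test()]) otherwise.
#' @noRd
wilcoxon_pratt <- function(d) {
  n0 <- sum(d == 0)
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  nn <- length(d)
  mu <- (nn * (nn + 1) - n0 * (n0 + 1)) / 4
  ties <- table(r[d != 0])
  v <- (nn * (nn + 1) * (2 * nn + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(ties^3 - ties) / 48
  if (v <= 0) return(list(statistic = wpos, p = 1))
  z <- (wpos - mu - sign(wpos - mu) * 0.5) / sqrt(v)
  list(statistic = wpos, p = min(1, 2 * pnorm(-abs(z))))
}

#' Paired comparison of two metric vectors
#'
#' Runs the normality gate on `a - b`, then a two-sided paired t-test
#' (gate passes) or Wilcoxon signed-rank test (gate fails; exact p for
#' n <= 25 without zeros/ties, Pratt's method with zeros).  All-zero
#' differences return `p = 1` with a degeneracy flag.
#'
#' @param a,b equal-length paired samples (n >= 3).
#' @param metric,contrast labels carried into the output row.
#' @return one-row data frame: `metric`, `contrast`, `n`, `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`, `test`, `statistic`, `p`, `normality_p`,
#'   `degenerate`.
#' @export
paired_compare <- function(a, b, metric = "metric", contrast = "contrast") {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3) cmj_stop("need >= 3 complete pairs", "cmj_data_error")
  d <- a - b
  row <- data.frame(
    metric = metric, contrast = contrast, n = n,
    mean_a = mean(a), sd_a = sd(a), mean_b = mean(b), sd_b = sd(b),
    test = NA_character_, statistic = NA_real_, p = NA_real_,
    normality_p = NA_real_, degenerate = FALSE,
    stringsAsFactors = FALSE
  )
  if (all(d == 0)) {
    row$test <- "paired_t"; row$statistic <- 0; row$p <- 1
    row$degenerate <- TRUE
    return(row)
  }
  gate <- normality_gate(d)
  row$normality_p <- gate$p
  if (isTRUE(gate$normal)) {
    ht <- t.test(a, b, paired = TRUE)
    row$test <- "paired_t"
    row$statistic <- unname(ht$statistic)
    row$p <- ht$p.value
  } else {
    row$test <- "wilcoxon"
    if (any(d == 0)) {
      wt <- wilcoxon_pratt(d)
      row$statistic <- wt$statistic
      row$p <- wt$p
    } else {
      ht <- suppressWarnings(
        wilcox.test(a, b, paired = TRUE, exact = (n <= 25 && !anyDuplicated(abs(d))))
      )
      row$statistic <- unname(ht$statistic)
      row$p <- ht$p.value
    }
  }
  row
}

#' Full comparison matrix for an analyzed cohort
#'
#' Reproduces the study's contrast design on the cohort's best-trial
#' metrics and normalized waveforms:
#' \enumerate{
#'   \item jump height, contraction time, RSImod and F_TOTAL compared
#'     between sessions (T0 vs T1);
#'   \item per-limb, per-phase net impulse and per-limb net peak force:
#'     within-limb T0 vs T1 and between-limb at T0 and at T1;
#'   \item asymmetry indices compared between sessions;
#'   \item four SPM waveform contrasts: between-limb at T0, between-limb
#'     at T1, involved limb T0 vs T1, uninvolved limb T0 vs T1.
#' }
#' For every discrete contrast, `mean_a`/`mean_b` are the first/second
#' group named in the contrast label and positive t means a > b.
#'
#' @param cohort an analyzed cohort from [analyze_cohort()] (or any list
#'   with `$metrics` wide data frame and `$waveforms` nested list).
#' @param alpha significance level (uncorrected).
#' @param spm_method `"rft"` or `"perm"`.
#' @param seed RNG seed for the permutation branch.
#' @return list with `discrete` (data frame of comparisons) and `spm`
#'   (named list of four `cmj_spm` objects).
#' @export
comparison_matrix <- function(cohort, alpha = 0.05,
                              spm_method = "rft", seed = NULL) {
  m <- cohort$metrics
  t0 <- m[m$session == "T0", ]
  t1 <- m[m$session == "T1", ]
  common <- intersect(t0$athlete_id, t1$athlete_id)
  if (length(common) < 3) {
    cmj_stop("need >= 3 paired athletes for group contrasts", "cmj_data_error")
  }
  t0 <- t0[match(common, t0$athlete_id), ]
  t1 <- t1[match(common, t1$athlete_id), ]

  rows <- list()
  add <- function(a, b, metric, contrast) {
    rows[[length(rows) + 1L]] <<- paired_compare(a, b, metric, contrast)
  }

  for (met in c("jump_height", "contraction_time", "rsi_mod", "f_total")) {
    add(t0[[met]], t1[[met]], met, "T0_vs_T1")
  }
  phase_metrics <- c(
    paste0("imp_", c("unweighting", "braking", "propulsion")),
    "peak_force"
  )
  for (met in phase_metrics) {
    inv <- paste0(met, "_involved")
    uni <- paste0(met, "_uninvolved")
    add(t0[[inv]], t1[[inv]], met, "within_involved_T0_T1")
    add(t0[[uni]], t1[[uni]], met, "within_uninvolved_T0_T1")
    add(t0[[uni]], t0[[inv]], met, "between_limb_T0")
    add(t1[[uni]], t1[[inv]], met, "between_limb_T1")
  }
  for (met in paste0("ai_", c("imp_unweighting", "imp_braking",
                              "imp_propulsion", "peak_force"))) {
    add(t0[[met]], t1[[met]], met, "asymmetry_T0_T1")
  }
  discrete <- do.call(rbind, rows)

  wf <- cohort$waveforms
  pick <- function(limb, session) wf[[limb]][[session]][common, , drop = FALSE]
  spm <- list(
    between_limb_T0 = spm_paired_test(
      pick("uninvolved", "T0"), pick("involved", "T0"),
      alpha, spm_method, seed = seed),
    between_limb_T1 = spm_paired_test(
      pick("uninvolved", "T1"), pick("involved", "T1"),
      alpha, spm_method, seed = seed),
    within_involved_T0_T1 = spm_paired_test(
      pick("involved", "T0"), pick("involved", "T1"),
      alpha, spm_method, seed = seed),
    within_uninvolved_T0_T1 = spm_paired_test(
      pick("uninvolved", "T0"), pick("uninvolved", "T1"),
      alpha, spm_method, seed = seed)
  )
  list(discrete = discrete, spm = spm, n_pairs = length(common))
}
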