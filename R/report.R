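# Report rendering -----------------------------------------------------------
#
# All numbers in the rendered tables come from the analysis object; the
# renderer only formats (2 decimals for metrics, p to 3 decimals with
# "<0.001" below that).

#' @noRd
fmt_p <- function(p) {
  ifelse(!is.finite(p), "NA",
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' @noRd
fmt_mean_sd <- function(m, s) sprintf("%.2f ± %.2f", m, s)

#' Write the full report bundle for an analyzed cohort
#'
#' Produces, under `out_dir`:
#' \itemize{
#'   \item `metrics_by_session.csv` — best-trial metrics, one row per
#'     athlete and session;
#'   \item `table_performance.csv` — session means of jump height,
#'     contraction time, RSImod and F_TOTAL with p-values;
#'   \item `table_limb_kinetics.csv` — per-limb peak force and phase
#'     impulses with all within/between-limb p-values and asymmetry
#'     indices;
#'   \item `comparisons.csv` — the raw comparison matrix;
#'   \item `spm_<contrast>.json` — the four SPM results;
#'   \item `fig_spm_<contrast>.pdf` — waveform and t-field figures;
#'   \item `qc_log.json` — per-trial events and QC flags.
#' }
#'
#' @param res a `cmj_cohort_analysis`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$metrics, file.path(out_dir, "metrics_by_session.csv"),
            row.names = FALSE)
  write.csv(res$comparisons$discrete, file.path(out_dir, "comparisons.csv"),
            row.names = FALSE)

  disc <- res$comparisons$discrete
  perf <- do.call(rbind, lapply(
    c("jump_height", "contraction_time", "rsi_mod", "f_total"),
    function(met) {
      row <- disc[disc$metric == met & disc$contrast == "T0_vs_T1", ]
      data.frame(metric = met,
                 T0 = fmt_mean_sd(row$mean_a, row$sd_a),
                 T1 = fmt_mean_sd(row$mean_b, row$sd_b),
                 p = fmt_p(row$p), stringsAsFactors = FALSE)
    }
  ))
  write.csv(perf, file.path(out_dir, "table_performance.csv"),
            row.names = FALSE)

  limb_rows <- list()
  for (met in c("peak_force", "imp_unweighting", "imp_braking",
                "imp_propulsion")) {
    wi <- disc[disc$metric == met & disc$contrast == "within_involved_T0_T1", ]
    wu <- disc[disc$metric == met & disc$contrast == "within_uninvolved_T0_T1", ]
    b0 <- disc[disc$metric == met & disc$contrast == "between_limb_T0", ]
    b1 <- disc[disc$metric == met & disc$contrast == "between_limb_T1", ]
    ai_name <- if (met == "peak_force") "ai_peak_force" else paste0("ai_", met)
    ai <- disc[disc$metric == ai_name & disc$contrast == "asymmetry_T0_T1", ]
    limb_rows[[met]] <- data.frame(
      metric = met,
      involved_T0 = fmt_mean_sd(wi$mean_a, wi$sd_a),
      involved_T1 = fmt_mean_sd(wi$mean_b, wi$sd_b),
      p_involved_T0_T1 = fmt_p(wi$p),
      uninvolved_T0 = fmt_mean_sd(wu$mean_a, wu$sd_a),
      uninvolved_T1 = fmt_mean_sd(wu$mean_b, wu$sd_b),
      p_uninvolved_T0_T1 = fmt_p(wu$p),
      p_between_T0 = fmt_p(b0$p), p_between_T1 = fmt_p(b1$p),
      asym_T0 = fmt_mean_sd(ai$mean_a, ai$sd_a),
      asym_T1 = fmt_mean_sd(ai$mean_b, ai$sd_b),
      p_asym = fmt_p(ai$p),
      stringsAsFactors = FALSE
    )
  }
  write.csv(do.call(rbind, limb_rows),
            file.path(out_dir, "table_limb_kinetics.csv"), row.names = FALSE)

  for (nm in names(res$comparisons$spm)) {
    spm <- res$comparisons$spm[[nm]]
    jsonlite::write_json(
      spm_as_json(spm, nm),
      file.path(out_dir, paste0("spm_", nm, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    p <- plot_spm_contrast(res, nm)
    pdf(file.path(out_dir, paste0("fig_spm_", nm, ".pdf")),
        width = 7, height = 6)
    print(p)
    dev.off()
  }

  jsonlite::write_json(res$qc, file.path(out_dir, "qc_log.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' @noRd
spm_as_json <- function(spm, contrast) {
  list(
    contrast = contrast, n = spm$n, nu = spm$nu, fwhm = spm$fwhm,
    resels = spm$resels, alpha = spm$alpha, method = spm$method,
    t_star = spm$t_star,
    clusters = lapply(seq_len(nrow(spm$clusters)), function(i) {
      cl <- spm$clusters[i, ]
      list(start_pct = cl$start_pct, end_pct = cl$end_pct,
           extent = cl$extent, p = cl$p)
    }),
    t_field = spm$t
  )
}

#' Two-panel SPM figure for one cohort contrast
#'
#' Top panel: group mean +/- SD of the two compared waveforms over
#' normalized movement time.  Bottom panel: the paired t-field with
#' symmetric dashed critical thresholds and suprathreshold clusters
#' shaded.
#'
#' @param res a `cmj_cohort_analysis`.
#' @param contrast one of the four SPM contrast names.
#' @return a patchwork/ggplot object.
#' @export
plot_spm_contrast <- function(res, contrast) {
  spm <- res$comparisons$spm[[contrast]]
  wf <- res$waveforms
  groups <- switch(contrast,
    between_limb_T0 = list(a = wf$uninvolved$T0, b = wf$involved$T0,
                           labs = c("uninvolved T0", "involved T0")),
    between_limb_T1 = list(a = wf$uninvolved$T1, b = wf$involved$T1,
                           labs = c("uninvolved T1", "involved T1")),
    within_involved_T0_T1 = list(a = wf$involved$T0, b = wf$involved$T1,
                                 labs = c("involved T0", "involved T1")),
    within_uninvolved_T0_T1 = list(a = wf$uninvolved$T0, b = wf$uninvolved$T1,
                                   labs = c("uninvolved T0", "uninvolved T1"))
  )
  common <- intersect(rownames(groups$a), rownames(groups$b))
  node <- 0:(length(spm$t) - 1)
  band <- function(mat, lab) {
    data.frame(node = node, mean = colMeans(mat),
               sd = apply(mat, 2, sd), group = lab)
  }
  df <- rbind(band(groups$a[common, , drop = FALSE], groups$labs[1]),
              band(groups$b[common, , drop = FALSE], groups$labs[2]))
  p1 <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$node, y = .data$mean, colour = .data$group,
    fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = NULL, y = "force (N/kg)", colour = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "top")

  tdf <- data.frame(node = node, t = spm$t)
  p2 <- ggplot2::ggplot(tdf, ggplot2::aes(x = .data$node, y = .data$t)) +
    ggplot2::geom_line(linewidth = 0.7)
  if (nrow(spm$clusters)) {
    p2 <- p2 + ggplot2::geom_rect(
      data = spm$clusters,
      ggplot2::aes(xmin = .data$start_pct, xmax = .data$end_pct),
      ymin = -Inf, ymax = Inf, alpha = 0.25, fill = "grey40",
      inherit.aes = FALSE
    )
  }
  p2 <- p2 +
    ggplot2::geom_hline(yintercept = c(-1, 1) * spm$t_star,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "movement (%)", y = "SPM{t}") +
    ggplot2::theme_minimal()
  patchwork::wrap_plots(p1, p2, ncol = 1) +
    patchwork::plot_annotation(title = gsub("_", " ", contrast))
}
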