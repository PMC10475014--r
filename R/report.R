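mean_sd <- function(x) {
  x <- x[is.finite(x)]
  c(mean = if (length(x)) mean(x) else NA_real_,
    sd = if (length(x) > 1) sd(x) else NA_real_,
    n = length(x))
}

# Paired effect size for one outcome across conditions; NA when fewer than
# two complete pairs or zero-variance differences.
paired_d_safe <- function(df, value_col) {
  wide <- merge(
    df[df$condition == "flash", c("participant", value_col)],
    df[df$condition == "placebo", c("participant", value_col)],
    by = "participant", suffixes = c("_flash", "_placebo")
  )
  fx <- wide[[paste0(value_col, "_flash")]]
  pl <- wide[[paste0(value_col, "_placebo")]]
  ok <- is.finite(fx) & is.finite(pl)
  if (sum(ok) < 2) return(NA_real_)
  diffs <- fx[ok] - pl[ok]
  if (sd(diffs) == 0) return(NA_real_)
  as.numeric(cohens_d_paired(diffs = diffs))
}

#' Assemble the study report
#'
#' Produces mean +/- SD summaries per condition for the phase outcomes
#' (phase change, net shift, phase angle, PRC-corrected shift), the
#' architecture metrics and the band powers, paired Cohen's d per outcome,
#' a Grubbs screen of the flash-visit phase angles, and the Bonferroni
#' thresholds used for sleep-staging (7 comparisons: 5 stage durations +
#' 2 transition types) and spectral (5 bands) families. Participants with
#' an incomplete visit pair are dropped from paired statistics with a
#' warning. Group inference (mixed models, Bayes factors) is deliberately
#' out of scope: the tidy tables are exported ready for such fits.
#'
#' @param phase_records Data.frame from [run_full_analysis()] /
#'   [analyze_phase_shifts()]: one row per participant x condition with
#'   `delta_phi`, `psi`, `net_shift`, optionally `corrected_shift`.
#' @param architecture Optional tidy data.frame (participant, condition,
#'   window, metric, value).
#' @param spectral Optional tidy data.frame (participant, condition,
#'   window, stage, band, power_uv2).
#' @param family_alpha Family-wise alpha for the Bonferroni thresholds.
#' @return A list of class `study_report`.
#' @export
summarize_cohort <- function(phase_records, architecture = NULL,
                             spectral = NULL, family_alpha = 0.05) {
  pr <- phase_records
  if (nrow(pr) < 1) stop("need at least one phase-shift record")
  complete <- intersect(pr$participant[pr$condition == "flash"],
                        pr$participant[pr$condition == "placebo"])
  if (length(complete) < length(unique(pr$participant)))
    warning("dropping participant(s) with incomplete visit pairs: ",
            paste(setdiff(unique(pr$participant), complete), collapse = ", "))

  phase <- list(
    delta_phi_flash = mean_sd(pr$delta_phi[pr$condition == "flash"]),
    delta_phi_placebo = mean_sd(pr$delta_phi[pr$condition == "placebo"]),
    net_shift = mean_sd(pr$net_shift[pr$condition == "flash"]),
    phase_angle = mean_sd(pr$psi[pr$condition == "flash"]),
    d_delta_phi = paired_d_safe(pr, "delta_phi")
  )
  if ("corrected_shift" %in% names(pr)) {
    phase$corrected_shift_flash <-
      mean_sd(pr$corrected_shift[pr$condition == "flash"])
    phase$d_corrected <- paired_d_safe(pr, "corrected_shift")
  }
  psis <- pr$psi[pr$condition == "flash" & is.finite(pr$psi)]
  grubbs <- if (length(psis) >= 3 && sd(psis) > 0) grubbs_test(psis) else NULL

  arch_summary <- NULL
  if (!is.null(architecture) && nrow(architecture) > 0) {
    keys <- unique(architecture[, c("window", "metric")])
    out <- list()
    for (i in seq_len(nrow(keys))) {
      sub <- architecture[architecture$window == keys$window[i] &
                          architecture$metric == keys$metric[i], ]
      for (cond in c("placebo", "flash")) {
        ms <- mean_sd(sub$value[sub$condition == cond])
        out[[length(out) + 1L]] <- data.frame(
          window = keys$window[i], metric = keys$metric[i],
          condition = cond, mean = ms["mean"], sd = ms["sd"],
          n = ms["n"], d = paired_d_safe(sub, "value"),
          row.names = NULL)
      }
    }
    arch_summary <- do.call(rbind, out)
  }

  spec_summary <- NULL
  if (!is.null(spectral) && nrow(spectral) > 0) {
    keys <- unique(spectral[, c("window", "stage", "band")])
    out <- list()
    for (i in seq_len(nrow(keys))) {
      sub <- spectral[spectral$window == keys$window[i] &
                      spectral$stage == keys$stage[i] &
                      spectral$band == keys$band[i], ]
      for (cond in c("placebo", "flash")) {
        ms <- mean_sd(sub$power_uv2[sub$condition == cond])
        out[[length(out) + 1L]] <- data.frame(
          window = keys$window[i], stage = keys$stage[i],
          band = keys$band[i], condition = cond,
          mean = ms["mean"], sd = ms["sd"], n = ms["n"],
          row.names = NULL)
      }
    }
    spec_summary <- do.call(rbind, out)
  }

  structure(
    list(
      phase = phase,
      grubbs_phase_angle = grubbs,
      architecture = arch_summary,
      spectral = spec_summary,
      thresholds = list(
        sleep_staging = bonferroni_alpha(family_alpha, 7, digits = 3),
        spectral = bonferroni_alpha(family_alpha, 5)
      ),
      n_complete = length(complete),
      metadata = list(
        prc_correction = "multiplicative: observed * PRC(psi_mean)/PRC(psi_i)",
        group_inference = "not computed here; export tables to lme4/BayesFactor"
      )
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  fmt <- function(ms) sprintf("%.3f +/- %.3f (n=%d)", ms["mean"], ms["sd"],
                              as.integer(ms["n"]))
  cat("Study report\n")
  cat("  net shift (flash - placebo):", fmt(x$phase$net_shift), "h\n")
  cat("  delta-phi flash:   ", fmt(x$phase$delta_phi_flash), "h\n")
  cat("  delta-phi placebo: ", fmt(x$phase$delta_phi_placebo), "h\n")
  cat("  phase angle psi:   ", fmt(x$phase$phase_angle), "h\n")
  if (!is.null(x$grubbs_phase_angle)) {
    g <- x$grubbs_phase_angle
    cat(sprintf("  Grubbs on psi: G = %.3f vs %.3f -> %s\n", g$statistic,
                g$critical, if (g$outlier) "outlier" else "no outlier"))
  }
  cat(sprintf("  Bonferroni thresholds: staging %.3f, spectral %.3f\n",
              x$thresholds$sleep_staging, x$thresholds$spectral))
  invisible(x)
}
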