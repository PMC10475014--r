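#' Circadian phase shift between two DLMO assessments
#'
#' Computes delta-phi = dlmo_baseline - dlmo_post on a common continuous
#' time axis. A phase delay (post DLMO later than baseline) yields a
#' negative value; an advance is positive.
#'
#' @param dlmo_baseline,dlmo_post DLMO times in hours (numeric or
#'   `dlmo_estimate` objects).
#' @return Phase shift in hours.
#' @export
#' @examples
#' phase_shift(21.0, 22.5)  # -1.5 h, a delay
phase_shift <- function(dlmo_baseline, dlmo_post) {
  as_hours(dlmo_baseline) - as_hours(dlmo_post)
}

#' Control-subtracted (net) phase shift
#'
#' Subtracts the phase change observed in the placebo condition from the
#' phase change after flashes, removing within-individual drift caused by a
#' circadian period differing from 24 h.
#'
#' @param delta_phi_flash,delta_phi_placebo Phase shifts in hours for the
#'   same participant.
#' @return Net shift in hours (negative = net delay attributable to the
#'   stimulus).
#' @export
net_shift <- function(delta_phi_flash, delta_phi_placebo) {
  delta_phi_flash - delta_phi_placebo
}

#' Phase angle of light stimulation
#'
#' Interval from the baseline-day DLMO to the onset of the experimental
#' light exposure (psi = stimulus_onset - dlmo_baseline). Positive when the
#' stimulus follows DLMO (the usual case); a negative value (stimulus before
#' DLMO) is allowed and flagged with a warning.
#'
#' @param dlmo_baseline Baseline DLMO, hours (numeric or `dlmo_estimate`).
#' @param stimulus_onset Stimulus onset, hours on the same axis.
#' @return Phase angle in hours.
#' @export
#' @examples
#' phase_angle(-2.5, 0.5)  # 3.0 h
phase_angle <- function(dlmo_baseline, stimulus_onset) {
  psi <- stimulus_onset - as_hours(dlmo_baseline)
  if (psi < 0)
    warning("stimulus precedes DLMO (negative phase angle)")
  psi
}

as_hours <- function(x) {
  if (inherits(x, "dlmo_estimate")) x$onset_time else as.numeric(x)
}

#' Construct a phase response curve
#'
#' A phase response curve (PRC) maps the circadian phase of light exposure
#' (hours after DLMO) to the expected phase shift (hours). Interpolation is
#' piecewise linear and strictly confined to the tabulated domain; queries
#' outside it are errors, never silent extrapolation. The published curve
#' used in the field is not shipped with the package: users supply their own
#' table (see [read_prc_csv()]); a small linear synthetic curve is included
#' for testing only.
#'
#' @param phase_h Hours after DLMO, strictly increasing.
#' @param shift_h Expected phase shift at each tabulated phase, hours.
#' @return An object of class `phase_response_curve`.
#' @export
#' @examples
#' prc <- phase_response_curve(1:5, -0.5 - 0.2 * ((1:5) - 2))
#' prc_predict(prc, 3)  # -0.7
phase_response_curve <- function(phase_h, shift_h) {
  phase_h <- as.numeric(phase_h)
  shift_h <- as.numeric(shift_h)
  if (length(phase_h) != length(shift_h)) stop("phase and shift lengths differ")
  if (length(phase_h) < 2) stop("need at least two PRC points")
  if (any(diff(phase_h) <= 0)) stop("PRC phases must be strictly increasing")
  structure(list(phase_h = phase_h, shift_h = shift_h),
            class = "phase_response_curve")
}

#' Evaluate a phase response curve
#'
#' @param prc A [phase_response_curve()].
#' @param phase Query phase(s), hours after DLMO; must lie inside the
#'   tabulated domain.
#' @return Predicted shift(s), hours.
#' @export
prc_predict <- function(prc, phase) {
  stopifnot(inherits(prc, "phase_response_curve"))
  if (any(phase < min(prc$phase_h) | phase > max(prc$phase_h)))
    stop(sprintf("phase angle outside PRC domain [%.3g, %.3g]",
                 min(prc$phase_h), max(prc$phase_h)))
  approx(prc$phase_h, prc$shift_h, xout = phase, method = "linear")$y
}

#' PRC-correct an observed phase shift for stimulus timing
#'
#' Rescales an individual's observed shift to the magnitude expected had
#' the stimulus been delivered at the cohort-mean phase angle:
#' `corrected = observed * PRC(psi_mean) / PRC(psi_i)`. The correction is
#' the identity when `psi_i == psi_mean`, preserves zero shifts, and is
#' scale-equivariant in the observed shift. (The multiplicative form is a
#' package design choice; it is recorded in run metadata because an
#' additive reading of the timing correction is also defensible.)
#'
#' @param observed_shift Observed phase shift, hours.
#' @param psi_i Individual phase angle, hours after DLMO.
#' @param psi_mean Cohort-mean phase angle, hours after DLMO.
#' @param prc A [phase_response_curve()] covering both phases.
#' @return Corrected shift, hours.
#' @export
#' @examples
#' prc <- phase_response_curve(1:5, -0.5 - 0.2 * ((1:5) - 2))
#' prc_correct(-1.0, 2, 3, prc)  # -1.0 * (-0.7 / -0.5) = -1.4
prc_correct <- function(observed_shift, psi_i, psi_mean, prc) {
  p_i <- prc_predict(prc, psi_i)
  p_m <- prc_predict(prc, psi_mean)
  if (p_i == 0)
    stop("PRC is zero at the individual phase angle; correction undefined")
  observed_shift * p_m / p_i
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs test: the statistic is the maximum absolute
#' standardized deviation G = max|x_i - mean| / sd, compared to the
#' critical value `((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` where `t`
#' is the upper `alpha/(2n)` quantile of Student's t with `n - 2` degrees
#' of freedom. Used here to screen phase angles of light application.
#'
#' @param values Numeric vector, n >= 3, not all equal.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `grubbs_test` with `statistic`, `critical`,
#'   `outlier_index` (NA if none), `outlier` (logical), `alpha`, `n`.
#' @export
#' @examples
#' grubbs_test(c(2, 3, 3, 4, 10))  # flags the 10
grubbs_test <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("Grubbs test requires n >= 3")
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("Grubbs test undefined for zero variance")
  dev <- abs(values - mean(values))
  G <- max(dev) / s
  tq <- qt(1 - alpha / (2 * n), df = n - 2)
  crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
  out <- G > crit
  structure(
    list(statistic = G, critical = crit,
         outlier_index = if (out) which.max(dev) else NA_integer_,
         outlier = out, alpha = alpha, n = n),
    class = "grubbs_test"
  )
}

#' @export
print.grubbs_test <- function(x, ...) {
  cat(sprintf("Grubbs test (n = %d, alpha = %g): G = %.4f, critical = %.4f\n",
              x$n, x$alpha, x$statistic, x$critical))
  if (x$outlier) {
    cat(sprintf("  outlier at index %d\n", x$outlier_index))
  } else {
    cat("  no outlier\n")
  }
  invisible(x)
}
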