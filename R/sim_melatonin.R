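#' Simulate a salivary melatonin profile
#'
#' Concentrations follow a near square-wave evening rise modeled as a
#' logistic sigmoid: `baseline + amplitude * plogis((t - midpoint) / rise)`,
#' multiplied by lognormal noise with the configured coefficient of
#' variation (unit mean). Sampling follows the protocol schedule in the
#' config (30-min intervals by default). The analytic time at which the
#' noise-free curve crosses the 2x-baseline DLMO threshold is returned as
#' ground truth: `midpoint + rise * qlogis(baseline / amplitude)`.
#'
#' @param config A [sim_config()].
#' @param participant Participant index (seeds the noise stream).
#' @param visit Visit index (seeds the noise stream).
#' @param midpoint Sigmoid midpoint, hours rel. HSOn; defaults to
#'   `config$true_dlmo`.
#' @param day Day tag used only to decorrelate the noise stream
#'   ("baseline" or "post").
#' @return A list with `series` (a [melatonin_series()]) and `truth`
#'   (midpoint, analytic `true_dlmo_crossing`, and `crossing_in_window`
#'   flag; the flag is FALSE with a warning when the sampling window misses
#'   the crossing).
#' @export
#' @examples
#' out <- gen_melatonin_profile(sim_config(seed = 42, noise_cv = 0))
#' out$truth$true_dlmo_crossing
gen_melatonin_profile <- function(config, participant = 1L, visit = 1L,
                                  midpoint = NULL, day = c("baseline", "post")) {
  validate_sim_config(config)
  day <- match.arg(day)
  if (is.null(midpoint)) midpoint <- config$true_dlmo
  times <- seq(config$sampling_start, config$sampling_end,
               by = config$sampling_interval / 60)
  daytime <- times <= config$daytime_until
  if (sum(daytime) < 3)
    stop("sampling schedule must include >= 3 daytime points before the rise")
  b <- config$baseline_daytime_level
  a <- config$onset_amplitude
  clean <- b + a * plogis((times - midpoint) / config$rise_duration)
  if (config$noise_cv > 0) {
    set.seed(derive_seed(config$seed, participant, visit,
                         purpose = if (day == "baseline") 1L else 2L))
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    noise <- rlnorm(length(times), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    conc <- clean * noise
  } else {
    conc <- clean
  }
  # Analytic crossing of the 2x-baseline threshold: amplitude*sigmoid = b.
  crossing <- if (a > b) {
    midpoint + config$rise_duration * qlogis(b / a)
  } else {
    NA_real_  # amplitude too small: the clean curve never doubles baseline
  }
  in_window <- is.finite(crossing) &&
    crossing >= config$sampling_start && crossing <= config$sampling_end
  if (!in_window)
    warning("sampling window does not cover the true threshold crossing")
  list(
    series = melatonin_series(times, conc, daytime),
    truth = list(midpoint = midpoint, true_dlmo_crossing = crossing,
                 crossing_in_window = in_window)
  )
}

#' Simulate a paired-visit cohort with known ground truth
#'
#' Generates, per participant, a placebo visit and a flash visit, each with
#' a baseline-day and a post-stimulus-day melatonin series (and optionally
#' hypnograms and stage probabilities). The flash visit's true phase change
#' is `shift_i + drift_i` with `shift_i ~ N(true_shift_mean,
#' true_shift_sd)`; the placebo visit's is `drift_i ~ N(0, drift_sd)`.
#' Because the drift term (circadian period mismatch) is a property of the
#' participant it is shared between visits, so the control-subtracted net
#' shift recovers `shift_i` exactly in the noise-free limit.
#'
#' @param config A [sim_config()]; `n_participants >= 2`.
#' @param include_sleep If TRUE, also generate hypnograms and stage
#'   probabilities per visit (EEG is generated separately by
#'   [gen_eeg()]/[simulate_study()] because of its size).
#' @param prob_confusion Confusion matrix for [gen_stage_probabilities()];
#'   default emulates a high-fidelity automatic scorer.
#' @return A list of class `sim_cohort`: `config`, `participants` (nested
#'   per-visit data), and `truth` (data.frame with one row per participant:
#'   true DLMO crossings, per-condition true phase changes, drift and
#'   `true_net_shift`).
#' @export
#' @examples
#' coh <- gen_cohort(sim_config(seed = 7, n_participants = 3),
#'                   include_sleep = FALSE)
#' coh$truth$true_net_shift
gen_cohort <- function(config, include_sleep = TRUE,
                       prob_confusion = default_confusion_matrix()) {
  validate_sim_config(config)
  if (config$n_participants < 2) stop("n_participants must be >= 2")
  n <- config$n_participants
  set.seed(config$seed)
  midpoints <- rnorm(n, config$true_dlmo, config$dlmo_between_sd)
  drifts <- rnorm(n, 0, config$drift_sd)
  shifts <- rnorm(n, config$true_shift_mean, config$true_shift_sd)
  flash_first <- runif(n) < 0.5  # randomized visit order

  participants <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    conds <- if (flash_first[i]) c("flash", "placebo") else c("placebo", "flash")
    visits <- list()
    row <- list(participant = i)
    for (v in 1:2) {
      cond <- conds[v]
      dphi_true <- if (cond == "flash") shifts[i] + drifts[i] else drifts[i]
      base <- gen_melatonin_profile(config, i, v, midpoint = midpoints[i],
                                    day = "baseline")
      post <- gen_melatonin_profile(config, i, v,
                                    midpoint = midpoints[i] - dphi_true,
                                    day = "post")
      visit <- list(condition = cond, visit_index = v,
                    melatonin_baseline = base$series,
                    melatonin_post = post$series,
                    truth = list(
                      true_dlmo_baseline = base$truth$true_dlmo_crossing,
                      true_dlmo_post = post$truth$true_dlmo_crossing,
                      true_delta_phi = dphi_true
                    ))
      if (include_sleep) {
        h <- gen_hypnogram(config, config$sleep_duration,
                           seed = derive_seed(config$seed, i, v, purpose = 3L))
        visit$hypnogram <- h
        visit$probabilities <- gen_stage_probabilities(
          h, prob_confusion,
          seed = derive_seed(config$seed, i, v, purpose = 4L))
      }
      visits[[cond]] <- visit
      row[[paste0("true_delta_phi_", cond)]] <- dphi_true
      row[[paste0("true_dlmo_baseline_", cond)]] <-
        base$truth$true_dlmo_crossing
      row[[paste0("true_dlmo_post_", cond)]] <- post$truth$true_dlmo_crossing
    }
    row$drift <- drifts[i]
    row$true_net_shift <- shifts[i]
    participants[[i]] <- list(id = i, visits = visits)
    truth[[i]] <- as.data.frame(row)
  }
  structure(
    list(config = config, participants = participants,
         truth = do.call(rbind, truth)),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d participants x 2 visits (seed %d)\n",
              length(x$participants), x$config$seed))
  invisible(x)
}
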