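#' Default per-epoch hypnogram transition matrix
#'
#' First-order Markov transition probabilities between sleep stages at 15-s
#' steps. Diagonals are strong (stages dwell for minutes), and the early
#' night is dominated by N2/N3 because the chain is started in N1 at sleep
#' onset and drains quickly into N2/N3 with slow return paths.
#'
#' @return 5x5 row-stochastic matrix with dimnames over W, N1, N2, N3, REM.
#' @export
default_transition_matrix <- function() {
  m <- matrix(c(
    # to:   W      N1     N2     N3     REM
    0.900, 0.080, 0.020, 0.000, 0.000,  # from W
    0.020, 0.850, 0.120, 0.000, 0.010,  # from N1
    0.005, 0.020, 0.945, 0.025, 0.005,  # from N2
    0.001, 0.004, 0.035, 0.960, 0.000,  # from N3
    0.010, 0.020, 0.020, 0.000, 0.950   # from REM
  ), nrow = 5, byrow = TRUE, dimnames = list(STAGES, STAGES))
  m
}

#' Default stage-dependent EEG band amplitude weights
#'
#' Relative amplitude (not power) of band-limited noise per sleep stage and
#' band, in microvolt-like units. N3 is strongly delta-dominant, N2 carries
#' sigma (spindle-band) power, wake carries alpha. These weights exist to
#' exercise the spectral pipeline with the correct rank structure, not to
#' model physiological waveforms.
#'
#' @return 5x5 numeric matrix, rows = stages (W, N1, N2, N3, REM),
#'   columns = bands (delta, theta, alpha, sigma, beta).
#' @export
default_stage_band_weights <- function() {
  w <- matrix(c(
    # delta theta alpha sigma beta
    2.0,  1.5,  4.0,  0.5,  2.0,   # W
    3.0,  4.0,  2.0,  0.5,  1.0,   # N1
    8.0,  4.0,  1.5,  3.0,  0.8,   # N2
    20.0, 4.0,  1.0,  1.5,  0.5,   # N3
    3.0,  4.0,  2.0,  0.5,  1.2    # REM
  ), nrow = 5, byrow = TRUE,
  dimnames = list(STAGES, c("delta", "theta", "alpha", "sigma", "beta")))
  w
}

#' Simulation configuration for a paired-visit flash-therapy study
#'
#' Bundles every parameter of the synthetic-data generator. Defaults encode
#' the source protocol: 30-min saliva sampling, intra-assay CV of 5.42%
#' (all samples of one participant run on the same plate), a true flash
#' effect of -1.13 +/- 1.27 h (negative = phase delay), placebo drift with
#' a 20-min SD, 10 participants, 8-h sleep episodes scored in 15-s epochs,
#' and PSG at 128 Hz resampled to 100 Hz downstream.
#'
#' @param seed Integer seed; every generator derives its stream from it.
#' @param n_participants Number of participants (two visits each).
#' @param baseline_daytime_level Daytime melatonin level, pg/mL.
#' @param onset_amplitude Nocturnal rise amplitude above baseline, pg/mL.
#'   The assay range is 0.78-50 pg/mL; defaults keep peak levels inside it.
#' @param true_dlmo Sigmoid midpoint of the melatonin rise, hours relative
#'   to habitual sleep onset (HSOn); negative = before HSOn.
#' @param rise_duration Time-scale of the sigmoidal rise, hours.
#' @param sampling_interval Saliva sampling interval, minutes.
#' @param sampling_start,sampling_end Saliva sampling span, hours rel. HSOn.
#' @param daytime_until Samples at or before this time (hours rel. HSOn) are
#'   flagged as daytime and feed the 2x-baseline threshold.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   assay noise (0 = noise-free).
#' @param true_shift_mean,true_shift_sd Mean/SD (hours) of the true flash
#'   induced phase shift; delays are negative.
#' @param drift_sd SD (hours) of the within-participant drift applied to
#'   both visits (circadian period differing from 24 h); mean zero.
#' @param dlmo_between_sd Between-participant SD (hours) of the sigmoid
#'   midpoint.
#' @param sleep_duration Scored sleep episode length, hours.
#' @param hypnogram_transition_matrix Row-stochastic 5x5 matrix over
#'   W, N1, N2, N3, REM at 15-s steps.
#' @param stage_band_weights 5x5 matrix of per-stage band amplitudes, see
#'   [default_stage_band_weights()].
#' @param eeg_fs EEG sampling rate in Hz (>= 100).
#' @param eeg_channels Channel labels to synthesize.
#' @param epoch_length Epoch length in seconds.
#' @param stimulus_onset Light stimulus onset, hours after HSOn.
#' @param stimulus_duration Stimulus duration, hours.
#'
#' @return An object of class `sim_config` (validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_participants = 4)
#' cfg$true_shift_mean
sim_config <- function(seed = 1L,
                       n_participants = 10L,
                       baseline_daytime_level = 2,
                       onset_amplitude = 30,
                       true_dlmo = -1.2,
                       rise_duration = 0.5,
                       sampling_interval = 30,
                       sampling_start = -8,
                       sampling_end = 4,
                       daytime_until = -6,
                       noise_cv = 0.0542,
                       true_shift_mean = -1.13,
                       true_shift_sd = 1.27,
                       drift_sd = 20 / 60,
                       dlmo_between_sd = 0.5,
                       sleep_duration = 8,
                       hypnogram_transition_matrix = default_transition_matrix(),
                       stage_band_weights = default_stage_band_weights(),
                       eeg_fs = 128,
                       eeg_channels = c("C3", "C4"),
                       epoch_length = 15,
                       stimulus_onset = 0.5,
                       stimulus_duration = 1) {
  cfg <- list(
    seed = as.integer(seed),
    n_participants = as.integer(n_participants),
    baseline_daytime_level = baseline_daytime_level,
    onset_amplitude = onset_amplitude,
    true_dlmo = true_dlmo,
    rise_duration = rise_duration,
    sampling_interval = sampling_interval,
    sampling_start = sampling_start,
    sampling_end = sampling_end,
    daytime_until = daytime_until,
    noise_cv = noise_cv,
    true_shift_mean = true_shift_mean,
    true_shift_sd = true_shift_sd,
    drift_sd = drift_sd,
    dlmo_between_sd = dlmo_between_sd,
    sleep_duration = sleep_duration,
    hypnogram_transition_matrix = hypnogram_transition_matrix,
    stage_band_weights = stage_band_weights,
    eeg_fs = eeg_fs,
    eeg_channels = eeg_channels,
    epoch_length = epoch_length,
    stimulus_onset = stimulus_onset,
    stimulus_duration = stimulus_duration
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants: positive sampling interval,
#' nonnegative noise CV, row-stochastic transition matrix (rows sum to 1
#' within 1e-9), nonnegative band weights, and an EEG rate of at least
#' 100 Hz.
#'
#' @param cfg A `sim_config` object.
#' @return `cfg`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.finite(cfg$sampling_interval) || cfg$sampling_interval <= 0)
    stop("sampling_interval must be > 0")
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0")
  if (cfg$n_participants < 1) stop("n_participants must be >= 1")
  tm <- cfg$hypnogram_transition_matrix
  if (!is.matrix(tm) || nrow(tm) != 5 || ncol(tm) != 5)
    stop("hypnogram_transition_matrix must be 5x5 over W,N1,N2,N3,REM")
  if (any(tm < 0)) stop("transition probabilities must be nonnegative")
  if (any(abs(rowSums(tm) - 1) > 1e-9))
    stop("each transition-matrix row must sum to 1 (within 1e-9)")
  w <- cfg$stage_band_weights
  if (!is.matrix(w) || nrow(w) != 5 || ncol(w) != 5)
    stop("stage_band_weights must be 5 stages x 5 bands")
  if (any(w < 0)) stop("stage_band_weights must be nonnegative")
  if (cfg$eeg_fs < 100) stop("eeg_fs must be >= 100 Hz")
  if (cfg$epoch_length <= 0) stop("epoch_length must be > 0")
  if (cfg$sampling_end <= cfg$sampling_start)
    stop("sampling_end must exceed sampling_start")
  invisible(cfg)
}

# Deterministic per-(participant, visit, purpose) substream seed derived from
# the master seed. Kept below 2^31 - 1.
derive_seed <- function(seed, participant, visit, purpose = 0L) {
  (as.integer(seed) + 7919L * as.integer(participant) +
     104729L * as.integer(visit) + 15485863L * as.integer(purpose)) %% 2147483629L
}
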