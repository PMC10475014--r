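# EEG synthesis: stage-weighted band-limited Gaussian noise.
#
# Per epoch, the signal is white noise shaped in the frequency domain by a
# gain that is the sum over bands of the stage's band amplitude weight times
# the band's indicator. Bands are de-overlapped for synthesis (alpha
# truncated to 7.5-12 Hz) so weights partition the spectrum; analysis bands
# keep the printed alpha/sigma overlap.
GEN_BANDS <- data.frame(
  band = c("delta", "theta", "alpha", "sigma", "beta"),
  low_hz = c(0.5, 3.5, 7.5, 12, 15),
  high_hz = c(3.5, 7.5, 12, 14, 30)
)

#' Simulate multichannel sleep EEG from a hypnogram
#'
#' Generates, per channel, stage-dependent band-limited Gaussian noise at
#' `config$eeg_fs`: within each epoch the spectrum of white noise is shaped
#' by the scored stage's band amplitude weights
#' (`config$stage_band_weights`), so e.g. N3 epochs are delta-dominant.
#' Signal continuity at epoch boundaries is not enforced. ARTIFACT epochs
#' (if present) produce zeros.
#'
#' @param h A [hypnogram()].
#' @param config A [sim_config()] (band weights, sampling rate, channels).
#' @param seed Integer seed; channels get decorrelated sub-streams.
#' @return Named list of [psg_signal()] objects (one per configured
#'   channel), starting at the hypnogram's start time.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' h <- gen_hypnogram(cfg, duration = 0.05, seed = 2)  # 12 epochs
#' sigs <- gen_eeg(h, cfg, seed = 3)
#' names(sigs)
gen_eeg <- function(h, config, seed) {
  stopifnot(inherits(h, "hypnogram"))
  validate_sim_config(config)
  if (length(h$stages) == 0) stop("zero-length hypnogram")
  fs <- config$eeg_fs
  spe <- round(h$epoch_length * fs)        # samples per epoch
  if (abs(spe - h$epoch_length * fs) > 1e-9)
    stop("epoch_length * eeg_fs must be an integer number of samples")
  n_e <- length(h$stages)
  w <- config$stage_band_weights

  # per-bin folded frequency and per-stage gain vectors (length spe)
  f <- (seq_len(spe) - 1) * fs / spe
  ff <- pmin(f, fs - f)
  gains <- matrix(0, spe, 5, dimnames = list(NULL, STAGES))
  for (b in seq_len(nrow(GEN_BANDS))) {
    inb <- ff >= GEN_BANDS$low_hz[b] & ff < GEN_BANDS$high_hz[b]
    for (s in seq_along(STAGES)) {
      gains[inb, s] <- gains[inb, s] + w[s, b]
    }
  }
  stage_idx <- match(h$stages, STAGES)     # NA for ARTIFACT
  out <- vector("list", length(config$eeg_channels))
  names(out) <- config$eeg_channels
  for (ch in seq_along(config$eeg_channels)) {
    set.seed((seed + 7654321L * ch) %% 2147483629L)
    noise <- matrix(rnorm(spe * n_e), spe, n_e)
    G <- matrix(0, spe, n_e)
    ok <- !is.na(stage_idx)
    G[, ok] <- gains[, stage_idx[ok], drop = FALSE]
    shaped <- Re(mvfft(mvfft(noise) * G, inverse = TRUE)) / spe
    out[[ch]] <- psg_signal(config$eeg_channels[ch], fs, as.vector(shaped),
                            start_time = h$start_time)
  }
  out
}
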