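#' Construct a PSG signal
#'
#' A single polysomnography channel: label, sampling rate, samples in
#' microvolts, and the start time of the first sample in hours relative to
#' HSOn.
#'
#' @param channel Channel label (e.g. "C3", "C4", "O1", "O2").
#' @param fs Sampling rate, Hz (> 0).
#' @param samples Numeric vector of samples, microvolts.
#' @param start_time Start time, hours rel. HSOn.
#' @return An object of class `psg_signal`.
#' @export
psg_signal <- function(channel, fs, samples, start_time = 0) {
  if (!is.finite(fs) || fs <= 0) stop("sampling rate must be > 0")
  samples <- as.numeric(samples)
  structure(
    list(channel = as.character(channel), fs = fs, samples = samples,
         start_time = start_time),
    class = "psg_signal"
  )
}

#' @export
print.psg_signal <- function(x, ...) {
  cat(sprintf("<psg_signal> %s: %d samples @ %g Hz (%.2f h) from %.2f h rel. HSOn\n",
              x$channel, length(x$samples), x$fs,
              length(x$samples) / x$fs / 3600, x$start_time))
  invisible(x)
}

#' Preprocess a PSG signal: band-pass and resample to 100 Hz
#'
#' Applies a zero-phase frequency-domain band-pass (raised-cosine
#' transitions, unity passband over [low, high] Hz, full stop below
#' `low/2` and above `high + 0.9` Hz — at least 20 dB down at 0.05 and
#' 50 Hz for the defaults) and resamples to `target_fs` by Fourier
#' resampling (spectral truncation/zero-padding), which is exact for the
#' band-limited signal and free of interpolation droop. Rates whose ratio
#' to `target_fs` is not a small rational fall back to linear
#' interpolation.
#'
#' @param signal A [psg_signal()] with `fs >= target_fs` (downsampling);
#'   set `upsample = TRUE` to allow slower inputs.
#' @param target_fs Output rate, Hz (default 100).
#' @param low,high Passband corners, Hz (defaults 0.2 and 49).
#' @param upsample Allow input rates below `target_fs`.
#' @return A [psg_signal()] at `target_fs`.
#' @export
preprocess_psg <- function(signal, target_fs = 100, low = 0.2, high = 49,
                           upsample = FALSE) {
  stopifnot(inherits(signal, "psg_signal"))
  x <- signal$samples
  bad <- which(!is.finite(x))
  if (length(bad) > 0)
    stop("non-finite samples at indices: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  if (signal$fs < target_fs && !upsample)
    stop("input rate ", signal$fs, " Hz below target ", target_fs,
         " Hz; pass upsample = TRUE to allow")
  if (high >= signal$fs / 2 || high >= target_fs / 2) {
    high <- min(high, signal$fs / 2 - 1, target_fs / 2 - 1)
  }
  n <- length(x)
  n_out <- floor((n - 1) * target_fs / signal$fs) + 1L
  # padded length m must make m * target_fs / fs an integer for spectral
  # resampling; k is the smallest such modulus
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  k <- signal$fs / g(signal$fs, target_fs)
  spectral_ok <- abs(k - round(k)) < 1e-9 && k <= 64
  if (spectral_ok) {
    k <- as.integer(round(k))
    m <- k * stats::nextn(ceiling(n / k), c(2, 3, 5))
  } else {
    m <- stats::nextn(n, c(2, 3, 5))
  }
  xp <- c(x, rep(0, m - n))
  f <- (seq_len(m) - 1) * signal$fs / m
  ff <- pmin(f, signal$fs - f)
  H <- band_transfer(ff, low, high)
  X <- fft(xp) * H
  if (spectral_ok) {
    m2 <- as.integer(round(m * target_fs / signal$fs))
    h <- m2 %/% 2
    Y <- complex(m2)
    nlow <- min(h + 1L, m %/% 2 + 1L)
    Y[seq_len(nlow)] <- X[seq_len(nlow)]
    ntop <- min(m2 - h - 1L, m - m %/% 2 - 1L)
    if (ntop > 0)
      Y[(m2 - ntop + 1L):m2] <- X[(m - ntop + 1L):m]
    y <- Re(fft(Y, inverse = TRUE)) / m
    y <- y[seq_len(n_out)]
  } else {
    filt <- Re(fft(X, inverse = TRUE))[seq_len(n)] / m
    t_in <- (seq_len(n) - 1) / signal$fs
    t_out <- (seq_len(n_out) - 1) / target_fs
    y <- approx(t_in, filt, xout = t_out, method = "linear",
                ties = "ordered")$y
  }
  psg_signal(signal$channel, target_fs, y, signal$start_time)
}

# Raised-cosine band-pass transfer function evaluated at folded
# frequencies ff: zero below lo_stop = low/2 and above hi_stop = high+0.9,
# unity over [low, high], half-cosine transitions between.
band_transfer <- function(ff, low, high) {
  lo_stop <- low / 2
  hi_stop <- high + 0.9
  H <- numeric(length(ff))
  pass <- ff >= low & ff <= high
  H[pass] <- 1
  ramp_up <- ff > lo_stop & ff < low
  H[ramp_up] <- 0.5 * (1 - cos(pi * (ff[ramp_up] - lo_stop) / (low - lo_stop)))
  ramp_dn <- ff > high & ff < hi_stop
  H[ramp_dn] <- 0.5 * (1 + cos(pi * (ff[ramp_dn] - high) / (hi_stop - high)))
  H
}

#' Welch power spectral density on 3-s Hamming windows
#'
#' Averages modified periodograms over non-overlapping 3-s Hamming-tapered
#' windows (300 samples at 100 Hz; frequency resolution 1/3 Hz). The
#' density is one-sided and window-gain corrected so that its integral over
#' frequency approximates the signal's mean square (Parseval). Segments are
#' not detrended: the upstream band-pass removes DC.
#'
#' @param x Numeric samples (or a [psg_signal()]).
#' @param fs Sampling rate, Hz (taken from the signal if one is given).
#' @param window_sec Window length in seconds (default 3).
#' @return An object of class `psd`: `freq` (Hz), `power` (uV^2/Hz),
#'   `fs`, `n_windows`.
#' @export
#' @examples
#' set.seed(1)
#' p <- welch_psd(rnorm(6000), fs = 100)
#' sum(p$power) * diff(p$freq[1:2])  # ~ 1 (unit variance)
welch_psd <- function(x, fs = 100, window_sec = 3) {
  if (inherits(x, "psg_signal")) {
    fs <- x$fs
    x <- x$samples
  }
  nw <- round(window_sec * fs)
  if (length(x) < nw)
    stop("segment too short: need >= ", window_sec, " s (", nw, " samples)")
  k <- floor(length(x) / nw)
  segs <- matrix(x[seq_len(k * nw)], nw, k)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(nw) - 1) / (nw - 1))  # Hamming
  X <- mvfft(segs * w)
  nb <- nw %/% 2 + 1L
  P <- rowMeans(Mod(X)^2)[seq_len(nb)]
  scale <- 2 / (fs * sum(w^2))
  psd <- P * scale
  psd[1L] <- psd[1L] / 2                       # DC not doubled
  if (nw %% 2 == 0) psd[nb] <- psd[nb] / 2     # Nyquist not doubled
  structure(
    list(freq = (seq_len(nb) - 1) * fs / nw, power = psd, fs = fs,
         n_windows = k),
    class = "psd"
  )
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d bins to %.4g Hz (df = %.4g Hz), %d windows\n",
              length(x$freq), max(x$freq), diff(x$freq[1:2]), x$n_windows))
  invisible(x)
}

#' Integrate a PSD over a frequency band
#'
#' Trapezoidal integral of the density over [low, high] Hz, with the band
#' edges linearly interpolated onto the frequency grid (no bin snapping).
#'
#' @param psd A [welch_psd()] result.
#' @param band Band name from [eeg_bands()], a numeric `c(low, high)`, or
#'   a one-row data.frame with `low_hz`/`high_hz`.
#' @return Band power in uV^2.
#' @export
#' @examples
#' set.seed(1)
#' p <- welch_psd(rnorm(6000), fs = 100)
#' band_power(p, "delta")
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd"))
  if (is.character(band)) {
    tab <- eeg_bands()
    row <- tab[tab$band == band, ]
    if (nrow(row) != 1) stop("unknown band name: ", band)
    lo <- row$low_hz; hi <- row$high_hz
  } else if (is.data.frame(band)) {
    lo <- band$low_hz[1]; hi <- band$high_hz[1]
  } else {
    lo <- band[1]; hi <- band[2]
  }
  if (hi <= lo) stop("band high must exceed low")
  if (hi > max(psd$freq) + 1e-9)
    stop(sprintf("band [%g, %g] extends beyond Nyquist (%g Hz)",
                 lo, hi, max(psd$freq)))
  f <- psd$freq
  p <- psd$power
  inner <- which(f > lo & f < hi)
  xf <- c(lo, f[inner], hi)
  yf <- c(approx(f, p, lo, ties = "ordered")$y, p[inner],
          approx(f, p, hi, ties = "ordered")$y)
  sum(diff(xf) * (head(yf, -1) + tail(yf, -1)) / 2)
}

#' Per-stage band powers within an analysis window
#'
#' Slices the hypnogram to the window, drops ARTIFACT epochs, pools each
#' scored stage's epochs across the window, computes one Welch PSD per
#' channel from the pooled 3-s windows (epochs are an exact multiple of
#' the 3-s window, so no window spans an epoch boundary), averages the
#' PSDs across channels, and integrates each band. Stages without
#' non-artifact epochs are omitted from the table.
#'
#' @param signals Named list of [psg_signal()]s (same rate and span);
#'   central channels C3 and C4 are used by default.
#' @param h A [hypnogram()] aligned to the signals.
#' @param window An [analysis_window()].
#' @param bands Band definition table (default [eeg_bands()]).
#' @param channels Channel labels to use (default `c("C3", "C4")`).
#' @return A data.frame with columns `window`, `channel`, `stage`, `band`,
#'   `power_uv2`, `n_epochs`; channel is `"central"` for the cross-channel
#'   average. Empty (with a warning) if every epoch is ARTIFACT.
#' @export
band_power_by_stage <- function(signals, h, window, bands = eeg_bands(),
                                channels = c("C3", "C4")) {
  stopifnot(inherits(h, "hypnogram"), inherits(window, "analysis_window"))
  have <- names(signals)
  use <- intersect(channels, have)
  if (length(use) == 0)
    stop("none of the requested channels present: ",
         paste(channels, collapse = ", "))
  sigs <- signals[use]
  fs <- sigs[[1]]$fs
  for (s in sigs) {
    if (s$fs != fs) stop("all channels must share one sampling rate")
  }
  hw <- slice_window(h, window)
  keep <- hw$stages != "ARTIFACT"
  if (!any(keep)) {
    warning("all epochs in window are ARTIFACT; empty band-power table")
    return(data.frame(window = character(), channel = character(),
                      stage = character(), band = character(),
                      power_uv2 = numeric(), n_epochs = integer()))
  }
  spe <- round(hw$epoch_length * fs)
  est <- epoch_starts(hw)
  rows <- list()
  for (stg in STAGES) {
    eidx <- which(hw$stages == stg)
    if (length(eidx) == 0) next
    # sample index blocks for this stage's epochs
    blocks <- lapply(est[eidx], function(t0) {
      s0 <- round((t0 - sigs[[1]]$start_time) * 3600 * fs) + 1L
      seq.int(s0, s0 + spe - 1L)
    })
    idx <- unlist(blocks)
    if (min(idx) < 1 || max(idx) > length(sigs[[1]]$samples))
      stop("signals do not cover the analysis window")
    psds <- lapply(sigs, function(s) welch_psd(s$samples[idx], fs = fs))
    pavg <- psds[[1]]
    if (length(psds) > 1) {
      pavg$power <- Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds)
    }
    for (b in seq_len(nrow(bands))) {
      rows[[length(rows) + 1L]] <- data.frame(
        window = window$label,
        channel = if (length(use) > 1) "central" else use,
        stage = stg,
        band = bands$band[b],
        power_uv2 = band_power(pavg, bands[b, ]),
        n_epochs = length(eidx)
      )
    }
  }
  do.call(rbind, rows)
}
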