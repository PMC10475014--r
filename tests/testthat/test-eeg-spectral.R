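sine <- function(freq, fs, dur, amp = 1) {
  amp * sin(2 * pi * freq * (0:(dur * fs - 1)) / fs)
}

test_that("preprocessing resamples to 100 Hz and preserves the passband", {
  x <- psg_signal("C3", 256, sine(2, 256, 60))
  y <- preprocess_psg(x)
  expect_equal(y$fs, 100)
  # passband gain: RMS amplitude within 2% (trim filter edge effects)
  core <- y$samples[500:(length(y$samples) - 500)]
  expect_equal(sqrt(mean(core^2)), 1 / sqrt(2), tolerance = 0.02)

  # 60 Hz mains contamination attenuated by >= 20 dB
  x60 <- psg_signal("C3", 256, sine(2, 256, 60) + sine(60, 256, 60))
  y60 <- preprocess_psg(x60)
  p <- welch_psd(y60)
  # above-passband residual vs the 2 Hz line
  hi <- band_power(p, c(45, 50))
  lo <- band_power(p, c(1.5, 2.5))
  expect_lt(hi / lo, 0.01)  # >= 20 dB down

  # zero in, zero out
  z <- preprocess_psg(psg_signal("C3", 200, rep(0, 2000)))
  expect_true(all(abs(z$samples) < 1e-12))

  # NaN samples are reported with indices
  bad <- psg_signal("C3", 200, c(1, NaN, 3, NA, 5))
  expect_error(preprocess_psg(bad), "indices: 2, 4")
  # upsampling requires the explicit flag
  slow <- psg_signal("C3", 64, rnorm(640))
  expect_error(preprocess_psg(slow), "upsample")
  expect_equal(preprocess_psg(slow, upsample = TRUE)$fs, 100)
})

test_that("Welch PSD satisfies Parseval and localizes pure tones", {
  set.seed(5)
  x <- rnorm(6000)  # 60 s at 100 Hz, unit variance
  p <- welch_psd(x, fs = 100)
  df <- diff(p$freq[1:2])
  expect_equal(df, 1 / 3)  # 3-s windows -> 1/3 Hz resolution
  expect_equal(sum(p$power) * df, 1.0, tolerance = 0.05)

  # 10 Hz sine: peak bin within one frequency-resolution step
  ps <- welch_psd(sine(10, 100, 30), fs = 100)
  expect_lte(abs(ps$freq[which.max(ps$power)] - 10), 1 / 3)

  # zero input -> identically zero PSD
  expect_true(all(welch_psd(rep(0, 1000), fs = 100)$power == 0))
  expect_error(welch_psd(rnorm(100), fs = 100), "too short")
})

test_that("band powers integrate the PSD over the printed bands", {
  # 2 Hz sine: nearly all 0.5-30 Hz power lands in delta
  p <- welch_psd(sine(2, 100, 60), fs = 100)
  delta <- band_power(p, "delta")
  total <- band_power(p, c(0.5, 30))
  expect_gte(delta / total, 0.95)

  # white noise: power ratio of two bands ~ bandwidth ratio 3:15
  set.seed(8)
  pw <- welch_psd(rnorm(60000), fs = 100)
  expect_equal(band_power(pw, "delta") / band_power(pw, "beta"),
               3 / 15, tolerance = 0.10)

  expect_equal(band_power(welch_psd(rep(0, 600), fs = 100), "alpha"), 0)
  expect_error(band_power(pw, c(40, 60)), "Nyquist")
  # the printed alpha/sigma overlap is preserved: both include 12-13 Hz
  b <- eeg_bands()
  expect_lt(b$low_hz[b$band == "sigma"], b$high_hz[b$band == "alpha"])
})

test_that("band power scales quadratically and is nonnegative", {
  set.seed(9)
  x <- rnorm(3000)
  p1 <- welch_psd(x, fs = 100)
  p3 <- welch_psd(3 * x, fs = 100)
  for (b in eeg_bands()$band) {
    expect_gte(band_power(p1, b), 0)
    expect_equal(band_power(p3, b), 9 * band_power(p1, b))
  }
})

test_that("per-stage band powers pool epochs within windows", {
  cfg <- sim_config(seed = 4)
  h <- hypnogram(c(rep("N3", 30), rep("N1", 9), "ARTIFACT"))
  sigs <- lapply(gen_eeg(h, cfg, seed = 5), preprocess_psg)
  w <- analysis_window("custom", start = 0, end = 40 * 15 / 3600)
  bp <- band_power_by_stage(sigs, h, w)
  # generator weights: N3 delta-dominant vs N1
  expect_gt(bp$power_uv2[bp$stage == "N3" & bp$band == "delta"],
            bp$power_uv2[bp$stage == "N1" & bp$band == "delta"])
  # ARTIFACT epochs are dropped, absent stages omitted
  expect_setequal(unique(bp$stage), c("N3", "N1"))
  expect_equal(unique(bp$n_epochs[bp$stage == "N3"]), 30)

  # single-epoch stage still yields a row
  h1 <- hypnogram(c(rep("N2", 19), "REM"))
  sigs1 <- lapply(gen_eeg(h1, cfg, seed = 6), preprocess_psg)
  w1 <- analysis_window("custom", start = 0, end = 20 * 15 / 3600)
  bp1 <- band_power_by_stage(sigs1, h1, w1)
  expect_true("REM" %in% bp1$stage)
  expect_equal(unique(bp1$n_epochs[bp1$stage == "REM"]), 1)

  # all-artifact window: empty table with a warning
  ha <- hypnogram(rep("ARTIFACT", 20))
  expect_warning(bpa <- band_power_by_stage(sigs1, ha, w1), "ARTIFACT")
  expect_equal(nrow(bpa), 0)
})

test_that("stage-pooled band powers sum close to signal variance", {
  # bands 0.5-30 Hz tile most of the filtered white spectrum; with a
  # 0.2-49 Hz band-limit the five printed bands capture the expected
  # fraction of total power (29.5+1 of ~48.8 Hz of flat spectrum).
  set.seed(10)
  x <- psg_signal("C3", 256, rnorm(256 * 120))
  y <- preprocess_psg(x)
  p <- welch_psd(y)
  tiled <- band_power(p, c(0.5, 30))
  total <- sum(p$power) * diff(p$freq[1:2])
  expect_equal(tiled / total, 29.5 / 48.8, tolerance = 0.05)
  expect_equal(total, var(x$samples) * 48.8 / 128, tolerance = 0.05)
})
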