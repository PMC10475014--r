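test_that("config invariants are enforced", {
  expect_error(sim_config(sampling_interval = 0), "sampling_interval")
  expect_error(sim_config(noise_cv = -0.1), "noise_cv")
  bad_tm <- default_transition_matrix(); bad_tm[1, 1] <- 0.5
  expect_error(sim_config(hypnogram_transition_matrix = bad_tm), "sum to 1")
  bad_w <- default_stage_band_weights(); bad_w[2, 3] <- -1
  expect_error(sim_config(stage_band_weights = bad_w), "nonnegative")
  expect_error(sim_config(eeg_fs = 50), "eeg_fs")
})

test_that("noise-free melatonin profiles recover the analytic crossing", {
  cfg <- sim_config(seed = 1, noise_cv = 0, baseline_daytime_level = 1,
                    onset_amplitude = 10, true_dlmo = -2)
  out <- gen_melatonin_profile(cfg)
  # analytic 2x-baseline crossing of the sigmoid
  expect_equal(out$truth$true_dlmo_crossing,
               -2 + cfg$rise_duration * qlogis(1 / 10))
  est <- estimate_dlmo(out$series, compute_threshold(out$series))
  expect_lt(abs(est$onset_time - out$truth$true_dlmo_crossing), 5 / 60)
})

test_that("melatonin generation is deterministic and warns off-window", {
  cfg <- sim_config(seed = 9)
  a <- gen_melatonin_profile(cfg, 3, 1)
  b <- gen_melatonin_profile(cfg, 3, 1)
  expect_identical(a$series$concentrations, b$series$concentrations)
  # different participant -> different noise stream
  c <- gen_melatonin_profile(cfg, 4, 1)
  expect_false(identical(a$series$concentrations, c$series$concentrations))
  # flat profile: no crossing exists, downstream errors
  cfg0 <- sim_config(seed = 1, noise_cv = 0, onset_amplitude = 0)
  expect_warning(out <- gen_melatonin_profile(cfg0), "does not cover")
  expect_true(is.na(out$truth$true_dlmo_crossing))
  expect_error(estimate_dlmo(out$series, compute_threshold(out$series)),
               "no onset")
  # crossing outside the sampling window is flagged
  cfgw <- sim_config(seed = 1, noise_cv = 0, true_dlmo = 7,
                     sampling_end = 2)
  expect_warning(gen_melatonin_profile(cfgw), "does not cover")
})

test_that("cohort true shifts match the configured effect scale", {
  cfg <- sim_config(seed = 21, n_participants = 200)
  coh <- gen_cohort(cfg, include_sleep = FALSE)
  expect_equal(nrow(coh$truth), 200)
  # CLT bound at n = 200, sd 1.27: |mean - (-1.13)| < 0.25 with margin
  expect_lt(abs(mean(coh$truth$true_net_shift) - (-1.13)), 0.25)
  # flash delta-phi = shift + drift; placebo delta-phi = drift
  expect_equal(coh$truth$true_delta_phi_flash -
                 coh$truth$true_delta_phi_placebo,
               coh$truth$true_net_shift)
  # degenerate: all participants identical when both SDs are zero
  cfg0 <- sim_config(seed = 2, n_participants = 5, true_shift_sd = 0,
                     drift_sd = 0, dlmo_between_sd = 0)
  coh0 <- gen_cohort(cfg0, include_sleep = FALSE)
  expect_true(all(coh0$truth$true_net_shift == -1.13))
  expect_error(gen_cohort(sim_config(n_participants = 1)), "n_participants")
})

test_that("DLMO parameter recovery holds at assay-level noise", {
  cfg <- sim_config(seed = 6, n_participants = 100, noise_cv = 0.09)
  coh <- gen_cohort(cfg, include_sleep = FALSE)
  errs <- vapply(coh$participants, function(p) {
    v <- p$visits$placebo
    est <- estimate_dlmo(v$melatonin_baseline,
                         compute_threshold(v$melatonin_baseline))
    abs(est$onset_time - v$truth$true_dlmo_baseline)
  }, 0)
  expect_lte(median(errs), 10 / 60)
})

test_that("hypnogram generation is a seeded Markov chain over 15-s epochs", {
  cfg <- sim_config(seed = 1)
  h <- gen_hypnogram(cfg, duration = 1, seed = 5)
  expect_equal(length(h$stages), 240)  # 3600 s / 15 s
  expect_identical(h$stages, gen_hypnogram(cfg, 1, seed = 5)$stages)
  expect_false(identical(h$stages, gen_hypnogram(cfg, 1, seed = 6)$stages))

  # identity transition matrix, started in N2, stays in N2
  id <- diag(5); dimnames(id) <- list(
    c("W", "N1", "N2", "N3", "REM"), c("W", "N1", "N2", "N3", "REM"))
  cfg_id <- sim_config(seed = 1, hypnogram_transition_matrix = id)
  expect_true(all(gen_hypnogram(cfg_id, 0.5, seed = 1,
                                start_stage = "N2")$stages == "N2"))
  expect_error(gen_hypnogram(cfg, duration = 0, seed = 1), "duration")
})

test_that("empirical transition rates match the chain within 3-sigma", {
  cfg <- sim_config(seed = 1)
  h <- gen_hypnogram(cfg, duration = 10000 * 15 / 3600, seed = 33)
  expect_equal(length(h$stages), 10000)
  tm <- cfg$hypnogram_transition_matrix
  stages <- c("W", "N1", "N2", "N3", "REM")
  a <- h$stages[-length(h$stages)]
  b <- h$stages[-1]
  for (from in stages) {
    n_from <- sum(a == from)
    if (n_from < 50) next  # too few visits for a binomial check
    for (to in stages) {
      p <- tm[from, to]
      obs <- sum(a == from & b == to)
      bound <- 3 * sqrt(n_from * p * (1 - p))
      expect_lte(abs(obs - n_from * p), max(bound, 3))
    }
  }
})

test_that("stage probabilities sum to 1 and track the confusion matrix", {
  cfg <- sim_config(seed = 1)
  h <- gen_hypnogram(cfg, duration = 4, seed = 2)
  p <- gen_stage_probabilities(h, seed = 3)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  expect_true(all(p >= 0 & p <= 1))

  # identity confusion -> exact one-hot vectors
  id <- diag(5)
  p1 <- gen_stage_probabilities(h, id, seed = 4)
  stages <- c("W", "N1", "N2", "N3", "REM")
  expect_true(all(p1[cbind(seq_len(nrow(p1)),
                           match(h$stages, stages))] == 1))

  # mean scored-stage probability approximates the diagonal of the
  # confusion matrix (e.g. 0.89 for wake under the default scorer model)
  cm <- default_confusion_matrix()
  for (s in c("N2", "N3")) {  # abundant stages
    sel <- h$stages == s
    expect_equal(mean(p[sel, s]), cm[s, s], tolerance = 0.02)
  }
  expect_error(gen_stage_probabilities(h, -id, seed = 1), "nonnegative")
})

test_that("EEG synthesis is seeded, stage-weighted, band-limited noise", {
  cfg <- sim_config(seed = 1)
  h <- hypnogram(rep(c("N3", "N1"), each = 10))
  a <- gen_eeg(h, cfg, seed = 5)
  b <- gen_eeg(h, cfg, seed = 5)
  expect_identical(a$C3$samples, b$C3$samples)
  expect_false(identical(a$C3$samples, a$C4$samples))

  # N3 delta weight 10x N1's -> delta power ranks N3 > N1 downstream
  w <- default_stage_band_weights()
  w["N3", "delta"] <- 10 * w["N1", "delta"]
  cfg10 <- sim_config(seed = 1, stage_band_weights = w)
  sigs <- gen_eeg(h, cfg10, seed = 6)
  pp <- lapply(sigs, preprocess_psg)
  bp <- band_power_by_stage(pp, h, analysis_window("custom", start = 0,
                                                   end = 20 * 15 / 3600))
  delta <- bp[bp$band == "delta", ]
  expect_gt(delta$power_uv2[delta$stage == "N3"],
            delta$power_uv2[delta$stage == "N1"])

  # all-zero weights -> identically zero signal
  cfg0 <- sim_config(seed = 1,
                     stage_band_weights = matrix(0, 5, 5,
                       dimnames = dimnames(default_stage_band_weights())))
  s0 <- gen_eeg(h, cfg0, seed = 7)
  expect_true(all(s0$C3$samples == 0))
})

test_that("serialized cohort output is byte-identical across reruns", {
  cfg <- sim_config(seed = 77, n_participants = 2, sleep_duration = 0.5)
  d1 <- file.path(tempdir(), "det_a")
  d2 <- file.path(tempdir(), "det_b")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_study(cfg, d1, include_eeg = FALSE)
  simulate_study(cfg, d2, include_eeg = FALSE)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
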