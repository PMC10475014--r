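test_that("DLMO threshold is twice the mean of the first daytime samples", {
  mk <- function(day_conc) {
    melatonin_series(seq(-8, -5, by = 1), c(day_conc, 9),
                     c(TRUE, TRUE, TRUE, FALSE))
  }
  expect_equal(compute_threshold(mk(c(1, 2, 3))), 4.0)
  expect_equal(compute_threshold(mk(c(1.0, 1.5, 0.5))), 2.0)
  # degenerate all-zero daytime: threshold 0 is rejected downstream
  s0 <- mk(c(0, 0, 0))
  expect_equal(compute_threshold(s0), 0)
  expect_error(estimate_dlmo(s0, compute_threshold(s0)), "threshold")
  # insufficient daytime baseline
  s1 <- melatonin_series(c(-8, -7, -6), c(1, 1, 5), c(TRUE, TRUE, FALSE))
  expect_error(compute_threshold(s1), "insufficient daytime")
  # a later daytime sample is ignored: only the first n_daytime count
  s2 <- melatonin_series(seq(-8, -4, by = 1), c(1, 2, 3, 100, 9),
                         c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(compute_threshold(s2), 4.0)
})

test_that("DLMO is linearly interpolated at the first sustained crossing", {
  # hand example: 20:00 -> 1.0, 20:30 -> 1.8, 21:00 -> 3.0 (times as hours)
  s <- melatonin_series(c(20, 20.5, 21), c(1.0, 1.8, 3.0), rep(FALSE, 3))
  est <- estimate_dlmo(s, 2.0)
  expect_equal(est$onset_time, 20.5 + 0.5 * (2.0 - 1.8) / (3.0 - 1.8))
  expect_equal(est$crossing_indices, c(2L, 3L))
  expect_true(est$onset_time >= s$times[2] && est$onset_time <= s$times[3])

  # sample landing exactly on the threshold is the onset
  s2 <- melatonin_series(c(0, 1, 2, 3), c(1, 2, 5, 8), rep(FALSE, 4))
  expect_equal(estimate_dlmo(s2, 2)$onset_time, 1)

  # flat series below threshold
  s3 <- melatonin_series(1:5, rep(1, 5), rep(FALSE, 5))
  expect_error(estimate_dlmo(s3, 2), "no onset")

  # series starting above threshold: rise not captured
  s4 <- melatonin_series(1:3, c(5, 6, 7), rep(FALSE, 3))
  expect_error(estimate_dlmo(s4, 2), "rise not captured")

  # a single-sample spike is skipped under the sustained rule but taken
  # as the onset under the plain first-crossing rule
  s5 <- melatonin_series(1:6, c(1, 5, 1, 1, 5, 6), rep(FALSE, 6))
  expect_equal(estimate_dlmo(s5, 4)$crossing_indices, c(4L, 5L))
  expect_equal(estimate_dlmo(s5, 4, sustained = FALSE)$crossing_indices,
               c(1L, 2L))
})

test_that("estimate_dlmo matches a brute-force adjacent-pair scan", {
  set.seed(42)
  for (rep in 1:1000) {
    rs <- random_series()
    thr <- runif(1, 0.5, max(rs$conc) * 1.2)
    expected <- oracle_dlmo(rs$times, rs$conc, thr)
    s <- melatonin_series(rs$times, rs$conc, rep(FALSE, length(rs$times)))
    if (is.na(expected)) {
      expect_error(estimate_dlmo(s, thr))
    } else {
      expect_equal(estimate_dlmo(s, thr)$onset_time, expected)
    }
  }
})

test_that("phase shift sign convention: delays are negative", {
  expect_equal(phase_shift(21.0, 22.5), -1.5)
  expect_equal(phase_shift(22.0, 21.5), 0.5)
  expect_equal(phase_shift(21.0, 21.0), 0)
  # antisymmetry
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(phase_shift(a, b), -phase_shift(b, a))
})

test_that("net shift subtracts the placebo change", {
  expect_equal(net_shift(-1.3, -0.2), -1.1)
  expect_equal(net_shift(-0.7, -0.7), 0)
  expect_equal(net_shift(-6.4, 0), -6.4)
})

test_that("phase angle is the DLMO-to-stimulus interval", {
  expect_equal(phase_angle(21.0, 24.0), 3.0)
  expect_equal(phase_angle(23.0, 23.0), 0)
  expect_warning(psi <- phase_angle(23.0, 22.0), "precedes")
  expect_equal(psi, -1.0)
})

test_that("Grubbs test flags a gross outlier and matches brute force", {
  g <- grubbs_test(c(2, 3, 3, 4, 10))
  expect_gt(g$statistic, g$critical)
  expect_equal(g$outlier_index, 5L)
  expect_equal(g$statistic, 1.7449, tolerance = 1e-4)
  expect_equal(g$critical, 1.7150, tolerance = 1e-4)

  g2 <- grubbs_test(c(1, 2, 3))
  expect_false(g2$outlier)

  expect_error(grubbs_test(c(5, 5, 5)), "zero variance")
  expect_error(grubbs_test(c(1, 2)), "n >= 3")

  set.seed(7)
  for (n in 3:30) {
    for (alpha in c(0.01, 0.05)) {
      x <- rnorm(n)
      if (runif(1) < 0.3) x[1] <- x[1] + 5  # sometimes plant an outlier
      ref <- oracle_grubbs(x, alpha)
      got <- grubbs_test(x, alpha)
      expect_equal(got$statistic, ref$G)
      expect_equal(got$critical, ref$crit)
      expect_identical(got$outlier, ref$outlier)
    }
  }
})

test_that("PRC interpolation is piecewise linear and domain-bounded", {
  prc <- phase_response_curve(1:5, -0.5 - 0.2 * ((1:5) - 2))
  expect_equal(prc_predict(prc, 2), -0.5)
  expect_equal(prc_predict(prc, 2.5), -0.6)
  expect_error(prc_predict(prc, 0.5), "outside PRC domain")
  expect_error(prc_predict(prc, 6), "outside PRC domain")
  expect_error(phase_response_curve(c(1, 1, 2), 1:3), "increasing")
})

test_that("PRC correction rescales shifts to the cohort-mean phase angle", {
  prc <- phase_response_curve(1:5, -0.5 - 0.2 * ((1:5) - 2))
  # hand example: observed -1.0 at psi 2, mean psi 3 -> -1.0 * (-0.7/-0.5)
  expect_equal(prc_correct(-1.0, 2, 3, prc), -1.4)
  # identity at the mean phase angle
  expect_equal(prc_correct(-0.8, 3.2, 3.2, prc), -0.8)
  # zero shifts stay zero
  expect_equal(prc_correct(0, 1.5, 4, prc), 0)
  # scale equivariance in the observed shift
  set.seed(3)
  for (i in 1:20) {
    obs <- rnorm(1); c <- runif(1, 0.1, 5)
    psi_i <- runif(1, 1, 5); psi_m <- runif(1, 1, 5)
    expect_equal(prc_correct(c * obs, psi_i, psi_m, prc),
                 c * prc_correct(obs, psi_i, psi_m, prc))
  }
  # zero PRC value at the individual's phase is an error
  prc0 <- phase_response_curve(c(0, 2, 4), c(-1, 0, 1))
  expect_error(prc_correct(-1, 2, 3, prc0), "zero")
})
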