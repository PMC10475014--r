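test_that("windows slice hypnograms by epoch start time, half-open", {
  h8 <- hypnogram(rep("N2", 8 * 240))  # 8-h record from HSOn
  expect_equal(length(slice_window(h8, analysis_window("intervention"))$stages),
               240)
  expect_equal(length(slice_window(h8, analysis_window("post"))$stages),
               1560)  # 6.5 h x 240
  expect_error(slice_window(h8, analysis_window("custom", start = -2,
                                                end = -1)),
               "does not overlap")
  # boundary epoch at exactly window end is excluded (half-open)
  h4 <- hypnogram(c("W", "N1", "N2", "N3"), epoch_length = 3600,
                  start_time = 0)
  sl <- slice_window(h4, analysis_window("custom", start = 0, end = 2))
  expect_identical(sl$stages, c("W", "N1"))
})

test_that("stage durations count epochs and conserve window time", {
  expect_equal(stage_durations(hypnogram(rep("N2", 240)))[["N2"]], 60)
  h <- hypnogram(c(rep("N2", 120), rep("N3", 80), rep("W", 40)))
  d <- stage_durations(h)
  expect_equal(unname(d[c("N2", "N3", "W")]), c(30, 20, 10))
  expect_equal(unname(d[c("N1", "REM")]), c(0, 0))

  # conservation incl. artifacts, over random hypnograms
  set.seed(11)
  for (i in 1:50) {
    h <- random_hypnogram()
    n_art <- sum(h$stages == "ARTIFACT")
    if (n_art == length(h$stages)) {
      expect_error(stage_durations(h), "ARTIFACT")
    } else {
      expect_equal(sum(stage_durations(h)),
                   (length(h$stages) - n_art) * h$epoch_length / 60)
    }
  }
})

test_that("durations are additive across disjoint windows", {
  set.seed(12)
  h <- random_hypnogram(n = 400, p_artifact = 0)
  w1 <- analysis_window("custom", start = 0, end = 0.4)
  w2 <- analysis_window("custom", start = 0.4, end = 400 * 15 / 3600)
  whole <- analysis_window("custom", start = 0, end = 400 * 15 / 3600)
  expect_equal(stage_durations(slice_window(h, w1)) +
                 stage_durations(slice_window(h, w2)),
               stage_durations(slice_window(h, whole)))
})

test_that("transition counts follow the stage taxonomy", {
  h <- hypnogram(c("N2", "N3", "N3", "N1", "W", "N1", "N2"))
  expect_equal(count_transitions(h, "deep_to_light"), 1)
  expect_equal(count_transitions(h, "sleep_to_wake"), 1)
  expect_equal(count_transitions(hypnogram(rep("N2", 10)), "deep_to_light"), 0)
  expect_equal(count_transitions(hypnogram(rep("N2", 10)), "sleep_to_wake"), 0)
  expect_equal(count_transitions(hypnogram(c("N3", "N2", "N3", "N1")),
                                 "deep_to_light"), 2)
  # alternative taxonomy: N2/N3 -> N1
  expect_equal(count_transitions(h, "deep_to_light",
                                 taxonomy = "n2n3_to_n1"), 1)
  expect_equal(count_transitions(hypnogram(c("N2", "N1", "N3", "N1")),
                                 "deep_to_light", taxonomy = "n2n3_to_n1"), 2)
  # artifacts break adjacency
  expect_equal(count_transitions(hypnogram(c("N3", "ARTIFACT", "N1")),
                                 "deep_to_light"), 0)
  expect_equal(count_transitions(hypnogram(c("N2", "ARTIFACT", "W")),
                                 "sleep_to_wake"), 0)
})

test_that("transition counting matches a brute-force pairwise scan", {
  set.seed(99)
  for (i in 1:1000) {
    h <- random_hypnogram()
    expect_equal(count_transitions(h, "deep_to_light"),
                 oracle_transitions(h$stages, "deep_to_light"))
    expect_equal(count_transitions(h, "sleep_to_wake"),
                 oracle_transitions(h$stages, "sleep_to_wake"))
    expect_equal(count_transitions(h, "deep_to_light",
                                   taxonomy = "n2n3_to_n1"),
                 oracle_transitions(h$stages, "deep_to_light",
                                    taxonomy = "n2n3_to_n1"))
  }
})

test_that("probability scoring averages the scored stage's probability", {
  h <- hypnogram(c("W", "W"))
  p <- stage_probabilities(rbind(c(0.89, 0.04, 0.02, 0.00, 0.05),
                                 c(0.64, 0.19, 0.03, 0.00, 0.14)))
  expect_equal(probability_score(p, h, "W"), 0.765)
  # absent stage: missing, not zero
  expect_true(is.na(probability_score(p, h, "REM")))

  # one-hot probabilities score exactly 1 for every present stage
  h2 <- hypnogram(c("N2", "N3", "N2", "REM"))
  onehot <- diag(5)[match(h2$stages, c("W", "N1", "N2", "N3", "REM")), ]
  p2 <- stage_probabilities(onehot)
  for (s in c("N2", "N3", "REM"))
    expect_equal(probability_score(p2, h2, s), 1)

  # misaligned lengths are an error
  expect_error(probability_score(p, h2, "N2"), "lengths differ")
  # rows must sum to one
  expect_error(stage_probabilities(rbind(c(0.5, 0.2, 0.1, 0.1, 0.05))),
               "sum to 1")
})

test_that("probability scores stay in [0, 1] and respect windows", {
  set.seed(13)
  cfg <- sim_config(seed = 13)
  h <- gen_hypnogram(cfg, duration = 2, seed = 14)
  p <- gen_stage_probabilities(h, seed = 15)
  w <- analysis_window("intervention")
  for (s in c("W", "N1", "N2", "N3", "REM")) {
    sc <- probability_score(p, h, s, w)
    if (!is.na(sc)) {
      expect_gte(sc, 0)
      expect_lte(sc, 1)
    }
  }
})
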