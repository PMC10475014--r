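Package: flashsleep
Title: Circadian Phase Shift and Sleep Analysis for Light-Flash Therapy Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for within-subject studies of circadian
    phase shifts induced by light exposure during sleep. Estimates dim
    light melatonin onset (DLMO) from salivary melatonin series using a
    participant-specific threshold, quantifies raw, control-subtracted,
    and phase-response-curve corrected phase shifts, screens phase angles
    with the Grubbs outlier test, computes hypnogram stage durations and
    stage-transition counts in protocol-defined analysis windows,
    summarizes per-epoch stage-probability scoring, and derives per-stage
    EEG band powers (delta, theta, alpha, sigma, beta) via Welch's method
    on 3-s Hamming windows. Includes paired-design effect-size and
    noncentral-t power computations, a seeded synthetic-data generator
    (melatonin profiles, Markov hypnograms, stage probabilities,
    band-limited EEG) with known ground truth, and a minimal EDF
    reader/writer for polysomnography signals.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
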