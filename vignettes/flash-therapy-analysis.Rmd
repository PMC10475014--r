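---
title: "Quantifying circadian phase shifts and sleep effects of light-flash therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circadian phase shifts and sleep effects of light-flash therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashsleep)
```

## The problem this package addresses

Brief flashes of bright light delivered through closed eyelids during sleep
can shift the human circadian clock, potentially by hours, without the
subject being awake for the exposure. Evaluating such an intervention in a
within-subject design requires four analysis stages, each with small but
consequential methodological choices:

1. **Circadian phase** is read from salivary melatonin: the dim light
   melatonin onset (DLMO) is the time the concentration rises above a
   participant-specific threshold. The phase shift is the difference
   between DLMOs measured on consecutive evenings, the control (placebo)
   night's change is subtracted to remove drift from a non-24-h intrinsic
   period, and shifts are rescaled by a phase response curve (PRC) to a
   common stimulus phase angle.
2. **Sleep architecture** from 15-s-epoch hypnograms: time in each stage,
   counts of deep-to-light and sleep-to-wake transitions, and—when the
   scorer emits per-epoch stage probabilities—the mean probability of each
   stage over the epochs scored as that stage.
3. **Spectral power** from central-derivation EEG: Welch periodograms on
   3-s Hamming windows, integrated over delta (0.5–3.5 Hz), theta
   (3.5–7.5 Hz), alpha (7.5–13 Hz), sigma (12–14 Hz) and beta (15–30 Hz),
   separately per scored stage within the intervention hour and the
   following 6.5 h.
4. **Paired statistics**: Cohen's d for paired designs, Bonferroni
   thresholds per outcome family, and exact noncentral-t power analysis
   (required n, minimal detectable difference).

Because no participant-level recordings are distributed with the protocol
this package re-implements, a seeded synthetic-data generator with known
ground truth stands in for raw data; every pipeline stage is validated
against that truth or against independent brute-force oracles.

## Time conventions

All times are continuous **hours relative to habitual sleep onset (HSOn)**
of the night under analysis. The evening melatonin rise therefore occurs at
negative times, the light stimulus at +0.5 h, and the scored sleep episode
over [0, 8] h. Mapping clock times onto this axis once, at ingest, removes
every midnight-wrap special case from the arithmetic.

## DLMO estimation

The participant-specific threshold is **twice the mean of the first three
daytime samples**. Two details are not fixed by the protocol text and are
package decisions:

* **Crossing rule.** "Exceeded" is read as the first *sustained*
  exceedance: the first run of consecutive samples at or above threshold
  that is at least two samples long (or reaches the end of the series,
  where sustainment cannot be refuted). A single-sample spike—whether in
  the middle or at the very start of the series—is treated as assay noise
  and skipped. `estimate_dlmo(..., sustained = FALSE)` restores the plain
  first-crossing rule.
* **Interpolation.** The onset time is linearly interpolated between the
  last sample below threshold and the first sample of the sustained run; a
  sample landing exactly on the threshold is itself the onset. With 30-min
  sampling, interpolation rather than sample-time assignment roughly halves
  the expected quantization error (≈7.5 min → a few minutes, see the
  recovery tests).

An error—not a fabricated time—results when the series never crosses the
threshold, or starts inside a sustained exceedance ("rise not captured").

## Phase shift, phase angle, and PRC correction

The phase shift is `delta_phi = DLMO_baseline − DLMO_post`; delays are
negative. The net shift subtracts the placebo visit's `delta_phi` from the
flash visit's, cancelling within-participant drift. The phase angle
`psi = stimulus_onset − DLMO_baseline` locates the stimulus on the PRC;
flash-visit phase angles are screened with a two-sided Grubbs test
(statistic `max|x−mean|/sd` against the t-derived critical value).

The timing correction is the one genuinely ambiguous computation: the
protocol describes using "a percentage of change from the average phase
shift". This package implements the **multiplicative** reading,

`corrected = observed × PRC(psi_mean) / PRC(psi_i)`,

which is the identity at the cohort-mean phase angle, preserves zero
shifts, and is scale-equivariant—properties an additive adjustment lacks
near zero shifts. The choice is recorded in every run's provenance record
so downstream users can see which variant produced their numbers. PRC
queries outside the tabulated domain are errors; the package never
extrapolates a PRC. The shipped `prc_linear_synthetic.csv` is a labelled
synthetic fixture for tests; real analyses must supply a published curve,
whose values are not redistributed here.

## Sleep architecture

Analysis windows are half-open, `[start, end)`, with epochs assigned by
their start time: this makes stage durations exactly additive across
adjacent windows. The protocol windows are the stimulus hour
[+0.5, +1.5) h and the post-stimulus [+1.5, +8.0) h.

Two published phrasings of "lightening" transitions exist—deep (N3) to
light (N2 or N1), and N2/N3 to N1. The N3-to-light definition is the
default; `taxonomy = "n2n3_to_n1"` selects the alternative, and the choice
is logged in the provenance record. ARTIFACT epochs are excluded from every
duration and probability metric, and they *break adjacency*: no transition
is counted into, out of, or across an artifact epoch, because an unknown
intervening state could hide any number of real transitions.

Probability scores average the scorer's probability of stage *s* over the
epochs scored *s*; a stage absent from a window yields a missing value, not
zero—absence of evidence is not a zero probability, and this mirrors the
reduced degrees of freedom such cells produce in downstream models.

## Spectral analysis

* **Preprocessing.** Signals are band-passed 0.2–49 Hz with a zero-phase
  frequency-domain filter (raised-cosine transitions, full stop below
  0.1 Hz and above 49.9 Hz; ≥20 dB attenuation at 0.05 and 50 Hz by
  construction) and resampled to 100 Hz by Fourier resampling, which is
  exact for the band-limited signal. Linear interpolation was rejected
  after testing: its sinc² droop loses ~17% of beta-band power at 30 Hz.
* **Welch estimator.** Non-overlapping 3-s Hamming windows (300 samples,
  1/3 Hz resolution), window-gain corrected so the PSD integrates to the
  signal's mean square. Segments are not detrended; the band-pass has
  already removed DC. Each 15-s epoch contains exactly five 3-s windows,
  so pooling epochs never creates a window spanning an epoch boundary.
* **Pooling order.** Within each analysis window, epochs are pooled by
  scored stage, one PSD is computed per channel from the pooled windows,
  PSDs are averaged across C3 and C4, and bands are integrated by
  trapezoid with interpolated band edges (no bin snapping). Averaging PSDs
  before integrating is equivalent to integrating then averaging (both are
  linear); it is done in this order so the per-stage PSD is available for
  inspection.
* **Bands.** The printed alpha (7.5–13) and sigma (12–14) bands overlap
  over 12–13 Hz; both are integrated as printed, with no de-overlap
  correction. The synthetic generator, in contrast, truncates alpha to
  7.5–12 Hz so its stage weights partition the spectrum.

## Paired statistics and power

Power computations use the exact noncentral t distribution (df `n−1`,
noncentrality `d√n`), two-sided tests throughout—the protocol states alpha
and power but not sidedness, and two-sided is the conservative reading.
`mdd_paired_t()` root-finds the smallest detectable mean difference;
`n_required_paired_t()` steps n upward. The minimal-detectable-wake
computation defaults to n = 6 pairs: seven participants had analyzable
polysomnography and one, already awake before the stimulus, is excluded.
Both landmark results—4.59 min detectable wake difference at SD 3.2 min,
and n = 4 for d = 2.77—are recomputed from these functions in the
acceptance tests, and the power function itself is checked against
100 000-replicate Monte-Carlo simulation.

## The synthetic-data generator: its stated world

Defaults encode the protocol's design: 10 participants, two visits in
randomized order, 30-min saliva sampling, 15-s epochs over an 8-h sleep
episode, stimulus at +0.5 h for 1 h, and a true flash effect of
−1.13 ± 1.27 h against placebo drift of SD 20 min.

Where the protocol gives no value, one realistic choice was made and
frozen:

* **Melatonin amplitude.** No amplitude is printed; the assay's working
  range is 0.78–50 pg/mL. Defaults are baseline 2 pg/mL and rise amplitude
  30 pg/mL, keeping nocturnal peaks inside the assay range—an explicitly
  flagged choice, not a protocol value.
* **Noise.** Multiplicative lognormal with CV 5.42% (the intra-assay CV):
  all samples of one participant are assayed on a single plate, so
  within-series scatter is intra-assay; the 8.9% inter-assay CV applies
  between participants, not within a series. Concentrations stay positive
  by construction.
* **Onset shape.** A logistic sigmoid (midpoint −1.2 h, time-scale 0.5 h)
  approximates the near-square-wave rise; the 2×-baseline crossing of the
  clean curve is analytically `midpoint + rise · qlogis(baseline/amplitude)`
  ≈ −2.5 h, which places the stimulus ≈3.0 h after DLMO, matching the
  reported cohort mean phase angle.
* **Sampling window.** Simulated sampling extends to HSOn + 4 h (beyond
  the baseline-evening protocol) so that delays up to ~6.5 h—the largest
  individual responses reported—keep the post-day crossing inside the
  sampled window.
* **Drift sharing.** The drift term is a property of the participant
  (their intrinsic period) and is applied to both visits, so the
  control-subtracted net shift recovers the true flash effect exactly in
  the noise-free limit; this is what the subtraction is for.
* **Hypnograms** are first-order Markov chains started in N1 with strong
  diagonals and an early-night drain into N2/N3. **Stage probabilities**
  are Dirichlet draws centered on a configurable scorer confusion matrix
  (concentration 50), so an identity confusion yields exact one-hot
  vectors. **EEG** is stage-weighted band-limited Gaussian noise—enough to
  give the spectral pipeline the correct rank structure (N3
  delta-dominant, N2 sigma-rich).

What the generator does **not** emulate—and what a green test therefore
does not establish: ultradian REM cycling, spindles/K-complexes or any
waveform morphology, circadian modulation of sleep propensity, scorer
artifacts correlated with arousals, or heavy-tailed assay error. Tests
certify the *computations*, not physiological realism.

## Numerical and format notes

* Determinism: every stochastic routine takes or derives an explicit seed;
  per-participant/visit/purpose substreams are derived from the master
  seed, so regenerating any single piece reproduces it bit-for-bit.
* EDF I/O is a minimal hand-written reader/writer (no EDF package exists
  in the target environment): continuous 16-bit signals, 1-s records.
  Quantization at the default ±400 µV range is ~0.012 µV, far below the
  synthetic noise floor; round-trip tests bound the error by one
  quantization step.
* `welch_psd` requires ≥300 samples; `band_power` refuses bands beyond
  Nyquist; PRC evaluation refuses out-of-domain queries; Grubbs requires
  n ≥ 3 and nonzero variance. Degenerate inputs error loudly rather than
  returning plausible numbers.

## Known limitations

Group-level inference (linear mixed models, Bayes factors) is deliberately
out of scope: the pipeline exports tidy per-participant tables ready for
`lme4`/`BayesFactor`, and the report's summaries are descriptive
(mean ± SD, paired d). Occipital channels are parsed but not analyzed by
default. The PRC correction's additive variant is not implemented, only
documented; users needing it can apply it to the exported `delta_phi` and
`psi` columns.
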