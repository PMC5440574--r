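---
title: "Modeling and decoding onset-dominant ILD coding in auditory cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and decoding onset-dominant ILD coding in auditory cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ildecode)
```

## The scientific question

Sound localization relies on interaural differences, and for
high-frequency sounds chiefly on the interaural level difference (ILD).
Perceptually, the binaural cues at a sound's onset dominate: a click
train whose *first* click carries a lateral ILD while the remaining
clicks carry 0 dB is heard well off midline, even though its average
physical cue is nearly zero.  Whether auditory-cortex BOLD responses
follow the physical cue or the onset-weighted percept is an empirical
question; this package provides a complete, testable model-and-analysis
chain for it.  Two hypotheses are built in as temporal weighting
functions over the 16 clicks of a train:

* **sensory** — uniform weights, `uniform_weights(16)`: the effective
  ILD of an onset-only train is 1/16 of its nominal value, so ILD
  tuning should collapse to a near-flat curve (the "1/16 scaled"
  expectation produced by `scaled_null_curve()`);
* **perceptual** — onset-dominant weights,
  `onset_dominant_weights(16)`: weight 0.4 on click 1, 0.4 shared by
  the last three clicks, the remainder spread over the middle.  The
  shape follows measured ILD temporal weighting functions, which show a
  large onset weight and a smaller recency contribution; no published
  numeric weights exist, so the vector is fully configurable and these
  defaults are a qualitative reconstruction.

The dot product `effective_ild(profile, w)` is linear in the profile,
so closed-form consequences follow directly: with all weight on click 1
the onset ILD is recovered exactly, and with weight 0.5/0.5 on the
first and last clicks the onset-only effective ILD is exactly half the
full-cue value — a 50% reduction in response modulation on any locally
linear stretch of tuning.

## Stimulus and design model

A Gabor click is a cosine at 4 kHz under a Gaussian envelope whose
half-power spectral width equals the requested 0.8-octave bandwidth
(`make_gabor_click()` enforces a sampling rate above twice the upper
spectral edge).  A train is 16 clicks at one per 2 ms — 32 ms nominal
duration — and each click's ILD `d` is realized by scaling the louder
ear by +d/2 dB and the other by −d/2 dB, preserving the average
binaural level (80 dB SPL, represented digitally against a configurable
full-scale reference, since digital audio has no absolute SPL).  Each
1-s trial is modeled as a single event: its sub-second four-interval
task structure is invisible at TR = 2 s, and the downstream beta
analysis is trial-level in any case.

Condition order follows a continuous-carryover (serially balanced)
design: an Eulerian circuit of the complete directed graph over the 10
conditions (nine ILDs plus a silent condition) with self-loops, each
arc duplicated `pair_multiplicity` times.  With multiplicity 2 this
gives exactly 200 trials, 20 per condition, and every ordered condition
pair exactly twice — checked exhaustively in the tests.  The sequence
is circular; `make_run_events(warmup = TRUE)` can prepend the final
element so every analyzed trial has a defined predecessor, standard
practice the design sources leave open.  Inter-trial gaps are uniform
on 0–5 s and task targets are flagged at about once per 13 s.  The
silent condition completes the design but is excluded from all tuning
and classification analyses (`filter_betas()`), and evokes zero
simulated amplitude.

Two printed stimulus facts are knowingly left as conventions rather
than targets: a "151-ms" individual-stimulus duration is inconsistent
with the 16-click/2-ms definition (32 ms), which the generator uses;
and a printed 2230-Hz bandwidth for 0.8 octaves at 4 kHz differs by
under 1% from the half-power convention used here (≈2246 Hz), a
Gaussian-parameterization difference with no analysis consequence.

## Hemodynamic model and single-trial estimation

The HRF is the difference of two gamma lobes with (time-to-peak, FWHM)
= (3.5, 5.2) s and (10.8, 7.35) s and an undershoot ratio of 0.35.
Each lobe converts (peak `p`, FWHM `w`) to gamma shape/scale by the
Gaussian approximation `shape = 8 ln 2 · (p/w)²`, `scale = p/shape`, a
standard convention where the originating toolbox leaves the mapping
unstated; a test pins the composite peak to 3.0–4.0 s.  The kernel is
normalized to unit maximum — another open convention (peak vs area
normalization); unit peak is chosen so simulated amplitudes and
estimated betas share units, making amplitude-recovery tests exact.
`h(0) = 0` and the default 30-s support contains the undershoot.

Single-trial amplitudes are estimated exactly as the measurement model
prescribes: the scans bracketing each trial's 12-s post-onset window
(±2 TR of context) are cubic-spline interpolated onto a 0.1-s grid
aligned at onset and regressed on an intercept plus the HRF on the same
grid.  The interpolation choice (natural cubic spline) is ours; only
"temporal interpolation" is prescribed.  The intercept is included —
also left open in the source procedure — because without it any
baseline offset biases betas; a test verifies betas are invariant to
constant shifts.  Two deliberate fidelity limits are documented rather
than fixed: neighbouring-trial overlap is *not* deconvolved (the
per-trial procedure shares this bias with the original analysis), and
spline reconstruction of the fast HRF rise from TR = 2 s samples
carries an onset-phase-dependent bias measured at ~1.2% on average
(worst case ~2.3%) on noiseless isolated trials.  Trials whose window
leaves the sampled run are flagged and excluded.

## Synthetic voxel populations

Each voxel responds to the effective ILD `x` with

```
baseline + slope · logistic((s·x − center)/width) + bump_amp · exp(−x²/(2·bump_width²))
```

where `s = ±1` encodes contralateral preference (left-hemisphere voxels
prefer rightward ILD).  ROI profiles follow the functional picture the
package is built to explore: Heschl's gyrus and posterior STG carry the
logistic slope; anterior STG is flat (slope and bump forced to zero),
serving as the negative control.  The midline bump term exists to model
the enhanced near-midline response seen for onset-only stimuli; its
relative amplitude is unquantified in the literature, so it defaults to
zero and is a free parameter for qualitative experiments.

Defaults and why:

* `n_per_roi = 100` voxels per ROI per hemisphere, 200 trials per run,
  TR = 2 s, nine subjects at two runs per mode in the full design —
  the scale of the motivating study at desktop cost.
* `sigmoid_width = 10` dB, centers jittered with SD 15 dB: population
  midpoints distributed across the ±30 dB stimulus range.  A nearly
  homogeneous population (centers within a few dB) is informationally
  redundant — every voxel carries the same signal — and decodes far
  below empirically reported levels; distributed midpoints are both the
  physiologically standard rate-code picture and what makes multi-class
  decoding behave realistically.
* `noise_sd = 0.5` (per scan, against response amplitudes of order 1),
  AR(1) coefficient 0.3.  AR(1) is the minimal temporally correlated
  noise model; the coefficient is a typical empirical lag-1 BOLD
  autocorrelation.  The noise level was calibrated once so that
  full-cue decoding of extreme ILDs sits in the empirically reported
  range (on the order of 20 points above the 11% chance level) and
  then frozen.

What the generator deliberately omits: spatial voxel correlations,
motion and physiological artifacts, scanner drift, surface geometry,
and any interhemispheric interaction.  Passing tests therefore
demonstrate the *pipeline's* correctness and calibration on a
plausible forward model — not that real cortex behaves this way.

## Statistics

**Tuning and ANOVA.** Betas are averaged across voxels within ROI per
trial, then across trials per condition, then across subjects
(`compute_tuning()`).  The ILD main effect uses one-way
repeated-measures ANOVA via `anova(lm(value ~ subject + level))`,
i.e. F with (8, 8(n−1)) degrees of freedom for nine levels — the
standard convention; published F(8,8) values with n = 9 reflect an
anomalous df convention we do not reproduce.  No sphericity correction
is applied, matching the uncorrected source convention.  Degenerate
zero-variance inputs return F = 0, p = 1 explicitly.  Null calibration
(uniform p under shuffled data) is asserted in the test suite by KS
test over 200 simulations.

**Side contrasts.** The nine levels partition into leftward
(−30, −20, −10), center (−5, 0, +5) and rightward (+10, +20, +30)
triplets; per-subject group means are compared between modes by paired
t-tests with Benjamini–Hochberg FDR at q = 0.05.  The FDR family is a
choice the source leaves open: `side_contrast()` adjusts within its own
three rows, and `adjust_contrast_family()` pools tables across ROIs and
hemispheres when the wider family is wanted.

**MVPA.** `run_mvpa()` repeats a stratified random half-split (training
halves stratified by class so no class is empty — the unstratified
variant risks degenerate folds), z-scores each voxel on training-half
statistics only, trains a linear libsvm SVM (one-vs-one, cost 1, the
library defaults, as only "a linear classifier" is prescribed), and
accumulates the test-half confusion matrix.  Per-class accuracy is
diagonal/row-sum; per-class RMS error is in dB of ILD, and
`rms_relative_to_chance()` reports null-mean minus observed so that
chance maps to 0 and positive values mean better than chance — our
reading of an ambiguously labelled "% RMS error" chance line.
`permutation_test()` shuffles labels (within run strata when given),
reruns the half-split machinery with a configurable, typically reduced,
repeat count (whether the original 1000 permutations re-ran all 1000
half-splits each is unstated), and forms add-one p-values
`(1 + #{null ≥ obs})/(1 + n_perm)`, which can never be 0.  Decoding is
run per subject with group-level aggregation (paired t-tests across
subjects via `compare_roi_accuracy()`), matching the paired inference
convention.

## The dissociation experiment

The headline property — reproduced as an acceptance test — is the
sensory/perceptual dissociation on onset-only runs: with onset-dominant
weights, extreme-ILD (±30 dB) decoding in a pSTG-profile population
beats the permutation null (p < 0.05 in all three seeded replicates at
two runs × 100 voxels, 49 permutations × 5 half-splits); with uniform
1/16 weights the same machinery finds nothing; and the flat
aSTG-profile control decodes at chance (overall accuracy within 3
points of 11%) under either weighting.  The same structure holds for
the univariate side: equal onset/offset weighting produces exactly a
50% reduction in onset-only modulation on a locally linear tuning
function, and uniform weighting produces the near-flat 1/16 curve.

## Numerical choices and problem sizes

All randomness flows through explicit integer seeds (sequence
construction, event jitter, noise, half-splits, permutations);
identical seeds give bit-identical outputs, which the tests assert.
Zero-variance features are guarded in z-scoring (SD 1 substituted),
all-identical feature matrices are rejected, permutation counts must be
positive, and the zero-variance paired-difference case in
`compare_roi_accuracy()` is flagged `degenerate` rather than silently
producing NaN.  The test suite and acceptance checks run at reduced
scale chosen as the package's own trade-off between statistical
resolution and desk cost: chance calibration uses 25 permutations × 10
half-splits on a 40-voxel single-ROI dataset; null-uniformity checks
use 200 reduced-scale simulations (nine classes × 4 trials × 5 voxels,
39 permutations); the dissociation uses three seeds at two runs × 100
voxels.  The defaults exposed to users (`n_repeats = 1000`,
`n_perm = 1000`) match the full-scale procedure.

## Known limitations

* Trial-overlap contamination is inherited by design from the
  per-trial estimation procedure; condition means remain rank-faithful
  (Spearman ρ > 0.9 against ground truth at default noise) but
  absolute betas are biased at short ITIs.
* The temporal weighting defaults are qualitative reconstructions, not
  fitted values.
* The generator's noise and tuning parameters are calibrated to
  reported group-level decoding levels, not to any subject-level data;
  quantitative agreement with real experiments should not be inferred.
* Only ILD is modeled; interaural time differences are out of scope.
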