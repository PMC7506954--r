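---
title: "Methods: classifying load position and weight during carrying gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying load position and weight during carrying gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(carrygait)
```

This vignette is the package's own account of its methods: the measurement
model it assumes, the generative model behind the synthetic cohort, the
statistics of the feature-selection and classification stages, and the
numerical conventions and open design decisions. Nothing here reports an
empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The measurement model

A *trial* is a single walk of roughly ten to fourteen steps while carrying
one of 19 load conditions (`load_conditions()`): no load, a 30-lb frontal
box with three left/right weight splits, or dumbbells of 0/5/15/25 lb per
hand. Two sensor streams are recorded on a shared trial clock (seconds from
trial start):

* **Kinematics** — 66 joint-angle channels (22 joints × 3 planes, degrees)
  at 240 Hz, plus heel-strike events `(time_s, side)`. The joint list
  follows the 23-segment/22-joint full-body model of commercial IMU
  motion-capture suits; since no flat channel grammar is prescribed by that
  model, this package fixes one: `<joint>|<plane>` (see
  `kinematic_channels()`). Sign convention: positive spine lateral bending
  leans toward the right.
* **EMG** — left and right erector spinae at 2148 Hz, in arbitrary
  amplitude units, plus one maximum-voluntary-contraction (MVC) reference
  recording per participant.

The two streams have different clocks rates, so step windows are located in
EMG by *time*, never by sample index; this avoids resampling entirely.
Either stream (but not both) may be missing for a trial; its features are
then zero-filled and flagged, mirroring the occasional loss of a sensor
system in practice.

## Five classification problems

Each condition maps to a class label or is skipped (`label_condition()`):

| id | classes | skipped |
|----|---------|---------|
| P1 | box / no box | — |
| P2 | box / 1 dumbbell / 2 dumbbells | no-load and the 3 symmetric pairs |
| P3 | symmetric / <20 lb / ≥20 lb difference | the 3 box trials |
| P4 | symmetric / ≤10 lb / >10 lb difference | the 3 box trials |
| P5 | symmetric / heavier left / heavier right | the 3 box trials |

Two conventions deserve comment. First, **P2**: the protocol contains nine
two-dumbbell conditions (three symmetric pairs and six asymmetric pairs),
but the per-class condition counts this analysis is defined by are 3/6/6.
Those counts are only attainable if the symmetric pairs are excluded, so P2
skips them and "2 dumbbells" means an asymmetric pair; `class_counts()`
asserts the 3/6/6 structure. Second, **P4's boundary** is ≤10 lb vs.
>10 lb; with the realized asymmetries {0×4, 5×2, 10×4, 15×2, 20×2, 25×2}
this is the only reading that produces the 4/6/6 split (a <10 vs. ≥10
boundary would give 4/2/10). Classes are coded 1..K in listing order; for
the asymmetry problems that order is ordinal in asymmetry, which is what
the regression-based machinery assumes.

## The synthetic cohort generator

`generate_cohort(n, generator_config(...))` draws participant-level random
effects (stride period 1.0–1.25 s, 10–14 steps per trial, per-joint
amplitude gains 0.85–1.15, per-channel posture offsets, EMG gain, per-muscle
MVC maxima), then synthesizes every trial:

* **Kinematics**: per channel, a truncated Fourier series (3 harmonics of
  the stride frequency, relative amplitudes 1/0.35/0.15, fixed per-channel
  phases with left/right anti-phase) scaled by a nominal per-joint amplitude
  loosely modeled on normative gait curves, gated on between the first and
  last heel strike with 0.4 s ramps, plus white measurement noise
  (`kinematic_noise_deg`, default 1°). Exact waveform shapes are free
  parameters: the pipeline only consumes per-step moments.
* **Heel strikes**: `n_steps + 1` alternating events every half stride with
  Gaussian timing jitter (`hs_jitter_s`, default 10 ms), bracketed by
  `standstill_pad_s` (default 1.5 s) of quiet standing.
* **Load effects on kinematics**: box carries add `box_arm_posture_deg`
  (default 70°) to both elbow flexion channels (a third of it to shoulder
  flexion) and suppress arm-swing amplitude; the whole frontal-carry
  postural effect scales with `box_arm_posture_deg`, so setting it to zero
  removes the box signature entirely (this is what the chance-recovery test
  exploits). A dumbbell of weight *w* on side *s* multiplies that side's
  arm-swing and wrist amplitudes by `max(0, 1 − rate·w)`
  (`armswing_suppression_per_lb`, `wrist_variability_suppression_per_lb`,
  defaults 0.03/lb). Asymmetric loads add a lateral trunk lean of
  `trunk_lean_deg_per_lb` (default 0.12°/lb) times the signed right-minus-
  left difference.
* **EMG**: one Gaussian burst per stance phase per muscle (centered 15 % of
  a stride after the same-side heel strike, σ = 8 % of a stride), with burst
  amplitude `base + a·own_load + b·contra_load` where the contralateral
  gain dominates (`emg_burst_base` 0.20, `emg_load_gain_per_lb` 0.004,
  `emg_contralateral_gain_per_lb` 0.012 — all on the normalized MVC scale).
  The carrier is band-limited (20–450 Hz) Gaussian noise scaled by
  √(π/2) so that the rectified-and-lowpassed envelope is an unbiased
  estimate of the modulation; `emg_noise_level` (default 0.02) adds a
  broadband floor. The MVC recording is a 5 s plateau at the participant's
  `mvc_max`, which guarantees that trial envelopes normalize into [0, 1]
  up to noise.

Randomness flows from one root seed: per-participant and per-trial child
seeds are derived arithmetically (`child_seed()`), so identical
configurations reproduce identical cohorts byte for byte.

**What the generator does *not* emulate** — and hence what passing tests do
not show about real data: soft-tissue artifact and IMU drift, within-trial
gait variability beyond white noise and timing jitter, foot-strike
biomechanics, genuine muscle-activation dynamics (the EMG is an
amplitude-modulated noise carrier), correlations between joints beyond
shared stride phase, and any participant anthropometry. Accuracies measured
on synthetic cohorts validate the *pipeline*, not the real-world
classification performance, which depends on the human dataset.

## EMG processing chain

Per channel: linear detrend → 2nd-order Butterworth 20–450 Hz bandpass →
full-wave rectification → 2nd-order Butterworth 10 Hz lowpass →
normalization by the MVC envelope maximum. Conventions, each chosen where
the procedure leaves room:

* Filters run forward–backward (`signal::filtfilt`), the standard offline
  practice; this doubles the effective order and makes the chain zero-phase.
* Detrending removes a linear trend, not just the mean.
* The envelope is clamped at zero (the lowpass can undershoot slightly).
* Peak "duration" is the width of the region where the envelope stays above
  the peak height minus half its topographic prominence, with interpolated
  crossings (the convention of common signal-processing toolboxes); an
  alternative supra-threshold-duration mode exists behind
  `duration_mode = "above_threshold"` and is excluded from acceptance
  checks. Peaks qualify at amplitude ≥ 10 % MVC and duration ≥ 0.2 s; the
  median of an even number of qualifying peaks is the midpoint of the two
  central values (R's default).

Analytic anchors verified by the tests: DC inputs produce an essentially
zero envelope; a unit 100 Hz sinusoid (near the bandpass center) produces a
steady-state envelope of 2/π; a 5 Hz tone is attenuated below 10 % of the
in-band response.

## Feature extraction

Per step and channel, four moments: mean and variance of the raw and of the
absolute signal. Variances use the sample (n − 1) denominator — the default
of this package's environment, documented so that a port using the
population denominator can reconcile. Per-step moments are averaged over
each side's steps ("per-step-then-average", the reading supported by the
procedure's phrasing), giving 264 per-step values and 528 per-trial
inertial features; EMG contributes 8 step-based features (mean/RMS per
muscle per step side) and 2 whole-trial peak medians. Samples belong to a
step when `start ≤ t < end`; half-open windows put every sample in exactly
one step. A trial side with no valid steps is zero-filled with a warning,
mirroring the zero-fill convention for lost sensors.

## Feature selection

The selection criterion is the **partial-F p-value of the candidate in an
OLS model of the integer class code** on the selected features plus
intercept. The procedure this package implements leaves the test statistic
behind "lowest p-value" open; the partial-F/OLS choice matches the
regression classifier family and the classic stepwise-regression heritage.

Floating search: add the minimum-p candidate while it beats the inclusion
threshold; after each inclusion, repeatedly remove the worst selected
feature whose removal p-value exceeds the exclusion threshold (equal to the
inclusion threshold), never removing the feature just added in the same
floating pass — that restriction guarantees termination, which an
unrestricted float does not. Ties are broken by canonical feature order;
collinearity is detected by a relative residual-sum-of-squares tolerance of
1e-10 (collinear or constant candidates get p = 1, perfect fits p = 0). An
iteration cap (2000) guards against pathological cycling; the cap has never
been reached in testing. If a run at 0.05 selects more than 50 features it
restarts from scratch at 0.01, then 0.001.

Selection scope: the default `"pooled"` mode selects once on the full
dataset *before* cross-validation — reproducing protocols that report a
single selected-feature count per problem, at the price of selection
leakage — while `"per_fold"` re-runs selection inside every training fold
and is leakage-free. Both are available in `lopo_cv()`; the acceptance
checks use the pooled mode for fidelity.

## Classifiers and cross-validation

All classifiers consume features z-scored with training-fold statistics
(zero-variance columns, e.g. zero-filled missing-sensor features, are left
at 0). REG is OLS on the class code with round-half-up prediction clipped
to [1, K]; rank-deficient designs fall back to the minimum-norm solution
with a warning. LDA uses pooled within-class covariance, ridge-regularized
by a 1e-6 trace fraction if singular — implemented in-package because that
regularization contract is not available in standard LDA routines, which
are instead used as an independent cross-check in the tests. The SVM is
linear-kernel, cost 1, one-vs-one for three classes (libsvm via e1071).
EDT is plain bagging: 100 depth-unlimited trees with `mtry = p` and a fixed
seed, so repeated runs are identical. Leave-participant-out CV holds out
each participant once; train/test participant disjointness is asserted in
every fold. An empty selected set (possible on null data) degrades to
predicting the training majority class.

## Design notes on the acceptance experiments

* The default configuration is the package's reference study condition:
  10 participants × 19 trials. On it, the frontal-carry problem is solved
  perfectly (the acceptance script recomputes this), and problem difficulty
  orders as P1 ≥ P2 ≥ the asymmetry problems.
* **Why the EMG lift concentrates on P5.** Under the generative model the
  burst gain is *linear* in (left load, right load), so every EMG feature
  is approximately linear in the two loads. The P3/P4 class codes are
  ordinal in |left − right|, which no linear function of linear features
  can represent — so the partial-F criterion on class codes cannot select
  EMG features for P3/P4 in expectation, and a linear classifier could not
  exploit them anyway. P5's heavier-side classes are monotone in the
  *signed* difference, which is linear in the loads; there the EMG features
  are selected and lift accuracy. The EMG-lift property is therefore
  assessed on the P3–P5 average with the linear SVM (the EMG-friendly
  classifier), under a configuration with weak kinematic asymmetry effects
  (trunk lean 0.02°/lb, arm-swing/wrist suppression 0.005/lb) and a strong
  contralateral EMG gain (0.02/lb) — quantities chosen once for that
  experiment, since the underlying procedure states only the qualitative
  directions of these effects.
* **Chance recovery.** With every load effect set to zero, all five
  problems' accuracies must lie within three binomial standard errors of
  their class-prior maximum; the empty-selection majority fallback and the
  adaptive threshold ladder make this stable.
* **Problem sizes in the test suite.** Unit tests run on 2–4-participant
  cohorts; the acceptance properties use 10-participant cohorts over five
  seeds (ordering) and five seeds (EMG lift), sizes chosen to keep the full
  suite comfortably reproducible on a single CPU while matching the
  reference cohort size where it matters.

## Known limitations

* The pooled selection mode is optimistically biased by construction; use
  `"per_fold"` for honest generalization estimates.
* The regression classifier is handicapped on P5, whose class coding is not
  ordinal in the signed load difference; this mirrors the behavior of the
  analysis it reimplements rather than a defect.
* The generator's effect sizes are phenomenological, not biomechanically
  derived; absolute synthetic accuracies should not be read as predictions
  of real-data accuracy.
* Skewness/kurtosis features and steady-state-only EMG re-extraction are
  deliberately out of scope.
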