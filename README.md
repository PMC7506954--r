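# carrygait

Classification of **how a load is carried during walking** — in front of the
body, in one hand, or in both hands, and how asymmetric the weight is — from
wearable-sensor recordings: full-body joint angles (22 joints × 3 anatomical
planes at 240 Hz) and bilateral erector spinae surface EMG (2148 Hz). The
package is aimed at human-movement and wearable-sensing researchers who want
a tested, reproducible reference implementation of this analysis, including a
seeded synthetic cohort generator so that every stage can be exercised and
validated without access to human data.

## The analysis

A trial is one walk across a laboratory while carrying one of 19 load
conditions (no load; a 30-lb box held in front with three left/right weight
splits; fifteen dumbbell combinations of 0/5/15/25 lb per hand). The pipeline:

1. **Step segmentation.** Heel-strike events split the trial into steps; a
   left→right heel-strike pair is a *right* step and vice versa
   (`segment_steps()`).
2. **Inertial features.** For each of the 66 joint-angle channels, the mean
   and variance of the raw and of the absolute signal are computed per step,
   then averaged over all left and all right steps separately:
   66 × 4 × 2 = **528 features** (`trial_inertial_features()`).
3. **EMG features.** Each EMG channel is linearly detrended, bandpassed
   20–450 Hz (2nd-order Butterworth, zero phase), rectified, enveloped with a
   10 Hz lowpass, and normalized by the participant's maximum voluntary
   contraction (MVC). Per-step mean and RMS averaged by step side give 8
   features; the median amplitude of envelope peaks (≥10 % MVC, ≥0.2 s) per
   muscle gives 2 more: **10 features** (`trial_emg_features()`).
4. **Feature selection.** Sequential floating forward selection: repeatedly
   add the feature with the smallest partial-F p-value in an OLS model of the
   integer class code,

   F = (RSS₀ − RSS₁) / (RSS₁ / (n − q − 2)),

   with conditional backward removal after each inclusion; the inclusion
   threshold adapts 0.05 → 0.01 → 0.001 whenever a run selects more than 50
   features (`sffs()`, `adaptive_select()`).
5. **Classification.** Four classifiers — regression-rounded least squares
   (REG), linear discriminant analysis (LDA), linear-kernel SVM, and a bagged
   100-tree ensemble (EDT) — evaluated by **leave-participant-out
   cross-validation** over five problems: box vs. no box (P1), box vs. one
   vs. two dumbbells (P2), and three load-asymmetry problems (P3–P5)
   (`lopo_cv()`, `run_pipeline()`).

The synthetic cohort generator (`generate_cohort()`) emulates the structure
this analysis relies on: truncated-Fourier gait waveforms with per-joint
phases, heel strikes with timing jitter, elevated elbow flexion and
suppressed arm swing for box carries, reduced arm-swing/wrist variability on
a loaded side, lateral trunk lean under asymmetric load, and burst-per-stance
EMG whose amplitude loads predominantly contralaterally.

## Worked example

```r
library(carrygait)

cohort   <- generate_cohort(4, generator_config(seed = 42))
features <- cohort_features(cohort)          # 76 trials x 538 features
res <- list(
  lopo_cv(features, "P1", "inertial", "REG"),
  lopo_cv(features, "P2", "inertial", "REG")
)
print(pipeline_report(res))
```

```
Leave-participant-out classification accuracy (%)
 problem   inertial emg both
      P1 14, 100.0%   -    -
      P2   4, 85.0%   -    -

Top selected features (inclusion order):
 P1: T1-C7|axial bending|raw|mean|Rsteps; L elbow|flexion/extension|raw|mean|Rsteps; ...
 P2: R shoulder|flexion/extension|abs|mean|Lsteps; L shoulder|flexion/extension|abs|mean|Rsteps; ...
```

Each cell shows "number of selected features, mean accuracy". On this small
4-participant cohort the frontal-carry problem (P1) is solved perfectly —
holding a box raises elbow flexion by tens of degrees and abolishes arm
swing, and the selected features are dominated by arm channels — while the
box/one-dumbbell/two-dumbbell problem (P2) reaches 85 %. Larger cohorts (the
default study size is 10 participants) tighten these estimates.

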