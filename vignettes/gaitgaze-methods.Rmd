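---
title: "Anticipatory gaze and gait around walk-mode transitions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anticipatory gaze and gait around walk-mode transitions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitgaze)
```

## The problem

When a walker approaches a terrain change — level ground to stairs, stairs to
level ground, on or off a ramp — the visual system reorients before the motor
system does: gaze drops toward the ground several steps before step length
and step timing adapt. `gaitgaze` implements a complete, testable pipeline
for this phenomenon: per-step gaze and gait deviation features from raw
wearable-sensor signals, stepwise statistics locating the onset of
anticipatory change, and a forecasting experiment asking whether a transition
can be predicted 1–4 steps ahead from a two-step feature window.

Every stage is validated against a synthetic data generator with *planted*
anticipatory dynamics, so the pipeline's recovery properties are measurable
rather than assumed.

## Signal model and feature definitions

**Steps.** A step runs from the first ground contact of one foot (rising
edge of a per-foot contact indicator, as produced by pressure insoles) to the
next first contact of the other foot. Two plausibility rules flag invalid
steps: consecutive contacts must alternate feet, and the swinging leg's
sagittal knee-angle maximum must fall within the central 10–90% of the step
period. Flagged steps are retained with `valid = FALSE`, never dropped, so
counts can be audited. Two contacts on the same frame invalidate both
adjacent steps (tie-break the source data leave open).

**Gait features.** Step length `l` is the full 3-D Euclidean distance
between the two contact positions (elevation included — on stairs the riser
is part of the step; the choice of 3-D over horizontal-plane distance is a
documented interpretation). Step period `p` is the contact-to-contact time.
Both are made dimensionless by Hof normalization, `l/L` and `p/sqrt(L/g)`
(leg length `L` in metres, `g` = 9.81 m/s²), and expressed as deviations
`dl_norm`, `dp_norm` from the participant's empirical level-walk baseline:
the mean over the designated baseline walk segment excluding its first and
last six steps, which are treated as transition-contaminated.

**Gaze features.** Eye pitch `theta` comes from the normalized vertical gaze
image coordinate through a linear map: image centre 0°, top edge `+vfov/2`,
bottom edge `-vfov/2`. The vertical field of view (`vfov`, default 82°) is a
configuration constant: only deviations from a within-participant baseline
are analysed, so it scales but cannot reorder effects. Head pitch `alpha` is
estimated from the head-mounted IMU by Madgwick's gradient-descent fusion —
gyroscope integration corrected toward the accelerometer gravity direction
with gain `beta` (default 0.1, with a 2 s burn-in discarded before baselines
are computed; zero-norm accelerometer samples get gyro-only updates). Both
angle series are smoothed with fourth-order Butterworth low-pass filters, 4 Hz
for head and 8 Hz for eye. Filtering is applied forward–backward
(zero-phase): a causal pass would delay the angle series by tens of
milliseconds and systematically shift anticipation onsets later, which is the
one bias this analysis cannot afford. Gaze pitch is the sum `gamma = theta +
alpha`, and the additivity `dgamma = dtheta + dalpha` is preserved exactly
through baselining and per-step averaging (means are linear). Per-step gaze
features are means over the step's frames `[t_contact, t_next_contact)`.

Positive pitch means looking up; anticipatory lowering of gaze appears as
negative deviations.

## Transition segmentation

Walk-mode labels are typically assigned by visual inspection and are
imprecise near boundaries. The pipeline refines them in two deterministic
stages:

1. **1-NN reassignment.** Frames at least six steps from every provisional
   boundary are high-confidence references; frames within six steps are
   reassigned the label of their nearest reference frame in z-scored
   six-dimensional joint-angle space (sagittal hip/knee/ankle, both legs).
   A mode that ends up with no reference frames (possible when jittered
   boundaries squeeze a short segment) keeps its provisional labels, with a
   warning. For tractability the reference set is thinned deterministically
   to at most `ref_max` (default 2000) frames before the scan.
2. **Run-length smoothing.** Per-step label runs shorter than two steps are
   merged into the preceding run. This replaces the manual correction of
   obvious outliers that a human annotator would perform, with a reproducible
   rule.

Each remaining label change yields a transition instance: the six valid,
consecutive steps before and after the change, indexed −6..−1, +1..+6 (there
is no step 0). Instances with any invalid step or missing feature are
discarded; changes closer than twelve steps to each other are both discarded.

**Outlier screening.** Within each transition category (ordered mode pair),
for every feature and every relative step index, values outside
`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` (type-7 quartiles, linear interpolation, fixed
for cross-platform reproducibility) are flagged, and an instance with any
flagged cell is removed. The grouping — per variable × step index within
category — and the instance-level removal keep the 12-step structure intact,
but the rule is aggressive: with 5 variables × 12 steps = 60 cells per
instance and small-sample quartile noise, roughly half of Gaussian-clean
instances are removed at 50 instances per category, more at smaller counts.
Study designs using this pipeline should budget for that loss (the package's
own tests plant 50 transitions per replicate). Whether the original
rule operated per cell, per step, or per instance is not determinable from
the source material; the instance-level choice is the conservative one for
downstream window construction.

## Stepwise statistics

For each variable (`dtheta`, `dalpha`, `dl_norm`, `dp_norm`) and category,
the per-instance values of consecutive steps from −6 to +3 are compared with
paired Wilcoxon signed-rank tests (zero differences discarded; `W` is the
smaller rank sum, so a unanimous shift gives W = 0; p-values from the normal
approximation with continuity correction). The Bonferroni family is the
eight consecutive-step pairs of one variable × category. Observations are
pooled across instances (hence across participants/laps); a per-participant
aggregation step would be a straightforward extension but halves the
effective sample at typical study sizes. Paired Cohen's d
(`mean(diff)/sd(diff)`) and percentile bootstrap CIs of the per-step means
(default 10,000 resamples in `bootstrap_ci`, 1,000 inside the batched test
table) are reported alongside. `earliest_significant_step` scans the pairs
from −6 forward and reports the most negative step whose comparison with the
next step is significant after correction — the operational "onset of
anticipatory change". Note the estimator's granularity: a deviation ramp
that begins at step −k first becomes *detectable* in the (−(k+1), −k) pair
when that pair is inside the tested range, and in the (−k, −k+1) pair
otherwise, so onsets are recovered to ±1 step by construction.

## Forecasting experiment

"Will a walk-mode transition occur in exactly `s` steps (s = 1..4), given the
previous two steps?" Each instance's six pre-transition steps yield five
2-step sliding windows (ends −5..−1); features are stacked oldest-first;
the window ending at step −s is the single positive. Negatives are the other
pre-transition windows of the same instances — steady-state windows far from
any transition are deliberately excluded (configurable by supplying other
instances), which makes the task "locate the transition within the approach
phase" rather than "detect an approach".

Class imbalance (1:4) is handled by SMOTE: synthetic minority samples
interpolated between a minority point and one of its five nearest minority
neighbours, up to 50% of the majority count, then random downsampling of the
majority to 1:1. Balancing is fitted inside each training fold only; test
folds are never touched (the fold bookkeeping is exposed for audit).

The classifier is a random forest (`ranger`, 200 trees, all features
candidate at each split — the configuration a grid search over
trees ∈ {10, 20, 100, 200, 300, 500} × features ∈ {sqrt, all} selects with
shared CV folds). Performance is Matthews' correlation coefficient, the
confusion-matrix correlation that stays informative under imbalance; a zero
denominator factor is defined as MCC = 0. Evaluation is 10-fold stratified
cross-validation repeated 10 times with per-repeat seeds derived from the
master seed by fixed offsets; fold assignment depends only on the labels and
the seed, so different feature sets evaluated under the same seed are paired
fold-by-fold.

Paired model comparisons use the corrected repeated k-fold CV t-test:
`t = mean(d) / sqrt((1/(k·r) + rho) · var(d))` with `rho = n_test/n_train =
1/(k − 1)` and df = k·r − 1. The correction compensates for the optimistic
variance of reused training data; with k = r = 10, df = 99. Its type-I error
is checked by simulation under the test's own dependence model — fold-score
differences with compound-symmetric correlation 1/k, the structure the
Nadeau–Bengio correction is built for — because simulating 200 full
double-CV classifier experiments would be computationally disproportionate
while measuring the same property of the test statistic.

## The synthetic generator

`generate_session` emits 60 Hz frames (contact indicators, 3-D foot
positions, hip/knee/ankle angles of both legs, head IMU, normalized gaze
coordinates, mode labels — plus direct pitch-angle columns so both the
raw-signal and the angle entry paths are exercised) for a configurable course
of walk/stairs/ramp segments, each at least 13 steps so a 6+6 window plus
baseline exclusions fit.

Planted structure, per transition category:

- **Gaze**: per-mode steady-state pitch holds (e.g. head −18°, eye −10° on
  descending stairs) plus a pre-transition ramp, linear in step index,
  starting `onset` steps out and reaching the category amplitude exactly one
  step before the boundary. Defaults: head onset 6 and amplitude −25° for
  walk→stairs-up, onset 5 / −32° for walk→stairs-down, eye onsets 4–5 with
  amplitudes −15 to −20°, ramps weak to nil. Linearity is a modelling
  choice; the observed growth is monotone without a stated functional form.
- **Gait**: the destination terrain's normalized shift (step length −0.25 to
  −0.30, period +0.06 to +0.08 for stairs; 0 for ramps) held over the whole
  new segment, approached by a linear ramp over the last `gait_onset`
  (default 2–3) steps.
- **Noise**: per-step Gaussian noise on each channel, defaults 2° for head
  and eye pitch, 0.04 for normalized step length, 0.06 for normalized step
  period. The period value matches normal stride-time variability (2–4% of a
  0.55 s step, i.e. ≈ 11–22 ms); anything much smaller is unrealistic at a
  60 Hz contact grid, where quantization alone contributes ≈ 16 ms
  peak-to-peak. Gaze-parameter variances per step are not reported in the
  source literature, so these magnitudes are free, stated parameters.

Numerical constructions worth knowing: contact events are snapped to the
frame grid (periods rounded to whole frames) and the *rounded* values are
recorded as ground truth, so quantization is part of the planted truth; pitch
traces are piecewise-constant per step, so with zero noise the planted
per-step means are exact up to the low-pass filter's smearing at step
boundaries (≤ 1.5° next to a 30° boundary jump, the tolerance stated in the
recovery test); stairs displace feet vertically by a 0.17 m riser and ramps
by a 6% grade, with the horizontal component reduced so the planted 3-D step
length is exact; IMU signals are synthesized from the head-pitch trace
(accelerometer = rotated gravity, gyroscope = pitch rate) in the same axis
convention the Madgwick extraction uses; eye pitch is inverted through the
same linear gaze-coordinate map the feature path applies.

`corrupt_labels` moves each true boundary by a uniform integer offset in
`[-w, +w]` steps (default 2), emulating annotation imprecision while keeping
ground truth in the session object.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: whole-body biomechanics (joint angles are
mode-typed templates, not dynamics), visual clutter and task-irrelevant gaze
(pedestrians, signage), sensor drift and magnetic disturbance in the IMU,
missed or spurious foot contacts (validity rules are exercised by
constructed fixtures instead), and any correlation structure between gaze
and gait noise. Effect recovery on synthetic data demonstrates that the
pipeline is correct and sensitive at the stated noise level, not that real
effects have the planted shape.

## Default problem sizes

The package's tests and examples run at desk scale, chosen to keep the whole
suite within a few minutes on one CPU while leaving comfortable statistical
margins: 50 planted transitions per replicate session for recovery and
forecasting checks (≈ 20–30 instances after IQR screening), 20 replicates for
onset recovery, 10 for the forecasting-ordering checks, 10×10-fold CV with
200 trees, 200 simulations for type-I error, and 100–10,000 bootstrap
resamples depending on context. `run_pipeline` defaults to 20 synthetic
sessions and the two stairs-approach categories.

## Known limitations

- The IQR screen's data loss (above) is the dominant driver of achievable
  instance counts; alternatives (cell-level masking, milder fences) would
  change downstream power and are not implemented.
- Pooling across participants in the stepwise tests treats instances as
  exchangeable; participant-level random effects are out of scope.
- The forecaster's negative class is confined to the six-step approach
  phase; deployment-style evaluation against long steady-state stretches
  would need those windows added.
- `earliest_significant_step` reports the first *pairwise* change; gradual
  drifts that never produce a significant single-pair difference are missed
  by design.
- The Madgwick implementation assumes an approximately constant sampling
  interval and handles accelerometer dropout (zero norm) but not gyroscope
  saturation.
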