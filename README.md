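# gaitgaze

Walkers do not change gait abruptly when the terrain changes: several steps
before stepping onto stairs or a ramp, gaze drops toward the ground, and only
one to three steps before the transition do step length and timing follow.
`gaitgaze` is an R package for quantifying that anticipatory cascade from
wearable-sensor recordings — head-mounted IMU and eye tracker plus foot
contact and position data — and for testing whether gaze makes walk-mode
transitions predictable several steps ahead. It is aimed at movement
scientists and at developers of walk-assist devices that must detect user
intent before the mechanical transition happens.

## What it computes

Per detected step (first ground contact of one foot to the next first contact
of the other foot), the package derives five deviation features against
per-participant level-walk baselines:

- **Gait** (Hof-normalized, dimensionless):
  Δl*ₙₒᵣₘ* = l/L − l₀ and Δp*ₙₒᵣₘ* = p/√(L/g) − p₀,
  with step length l, step period p, leg length L, g = 9.81 m/s².
- **Gaze** (degrees, positive = up): eye pitch θ (linear map from normalized
  gaze image coordinates), head pitch α (Madgwick orientation fusion of the
  IMU, 4 Hz zero-phase Butterworth), gaze pitch γ = θ + α, each as deviation
  Δθ, Δα, Δγ = Δθ + Δα from the level-walk baseline, averaged per step.

Around every walk-mode change it extracts 12-step transition instances
(steps −6..−1, +1..+6; IQR outlier screening), then answers two questions:

1. **When does behaviour start changing?** Wilcoxon signed-rank tests on each
   consecutive step pair from −6 to +3, Bonferroni-corrected per
   variable × category, with paired Cohen's d and bootstrap CIs, summarised
   as the earliest significant pre-transition step.
2. **Can transitions be forecast s steps ahead (s = 1..4)?** A random forest
   on 2-step feature windows, class-balanced with SMOTE inside the training
   folds, evaluated by Matthews' correlation coefficient
   MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN))
   under 10×10-fold stratified CV; feature sets (gaze, gait, both) are
   compared with the corrected repeated k-fold CV t-test
   (Nadeau–Bengio, df = k·r − 1).

Because the analyses need ground truth to be validated against, the package
ships a synthetic session generator (`generate_session`) that emits raw 60 Hz
multimodal frames for a configurable walk/stairs/ramp course with *planted*
anticipatory ramps (head pitch starting up to 6 steps out, gait 2–3 steps
out) and label jitter (`corrupt_labels`) mimicking imprecise manual
annotation. Every stage of the pipeline can therefore be checked against
known truth.

## Worked example

Fifty walk → stairs-up transitions with the default planted effects (head
pitch ramps to −25° over the 6 steps before the stairs, step length shortens
by 0.25 L over the last 2 steps, per-step noise 2° / 0.04):

```r
library(gaitgaze)

course <- course_spec(
  modes = c(rep(c("walk", "stairs_up"), 50), "walk"),
  n_steps = rep(13L, 101), baseline_segment = 1L)
session  <- generate_session(course, default_effects(), participant_params(),
                             seed = 42)
session  <- corrupt_labels(session, flip_window = 2, seed = 43)
features <- process_session(session$frames, leg_length = 0.9,
                            pipeline_config())
trans <- iqr_filter(extract_transitions(features))
up    <- trans[trans$category == "walk – stairs_up", ]

head_tests <- pairwise_stepwise_tests(up, "dalpha", seed = 1)
head_tests[, c("step_a", "step_b", "n", "W", "p_bonferroni", "d")]
#>   step_a step_b  n  W p_bonferroni      d
#> 1     -6     -5 17  0      0.00257 -2.082
#> 2     -5     -4 17  2      0.00368 -1.527
#> 3     -4     -3 17  5      0.00621 -1.550
#> 4     -3     -2 17  0      0.00257 -1.707
#> 5     -2     -1 17  5      0.00621 -1.391
#> 6     -1      1 17  0      0.00257  4.820
#> 7      1      2 17 40      0.70679  0.471
#> 8      2      3 17 46      1.00000 -0.309
earliest_significant_step(head_tests)
#> [1] -6
earliest_significant_step(pairwise_stepwise_tests(up, "dl_norm", seed = 1))
#> [1] -3
```

Head pitch already drops significantly between steps −6 and −5 (W = 0: every
instance moved the same way), while step length only changes from step −3 on
— the planted gaze-precedes-gait ordering is recovered. The same data feed
the forecasting experiment:

```r
gaze <- repeated_cv_evaluate(build_forecast_dataset(up, 3, "gaze"),
                             cv_config(k = 10, r = 10, seed = 9))
gait <- repeated_cv_evaluate(build_forecast_dataset(up, 3, "gait"),
                             cv_config(k = 10, r = 10, seed = 9))
ct <- corrected_cv_ttest(gaze, gait, k = 10, r = 10)
#> MCC at horizon 3: gaze 0.88, gait 0.19
#> corrected test t = 4.98, p = 2.7e-06, df = 99
```

Three steps ahead of the transition, gait features are still near baseline,
so the gait-only forecaster is close to chance (MCC 0.19) while the gaze-only
forecaster is strong (MCC 0.88) — the statistical ordering translates into
forecasting value. `run_pipeline(pipeline_config())` chains all stages
(simulate → features → transitions → stats → forecast) and writes the report
tables plus a run manifest.

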