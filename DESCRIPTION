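Package: gaitgaze
Title: Anticipatory Gaze and Gait Dynamics Around Walk-Mode Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing how gaze (eye and head pitch) and gait
    (Hof-normalized step length and period) change in the steps leading up
    to transitions between walk modes such as level walking, stairs and
    ramps. Provides a synthetic multimodal walking-session generator with
    planted anticipatory dynamics, step detection with plausibility
    validation, Madgwick IMU orientation estimation, zero-phase Butterworth
    smoothing, per-step feature extraction against level-walk baselines,
    12-step transition segmentation with IQR outlier removal, stepwise
    Wilcoxon signed-rank statistics with Bonferroni correction and
    bootstrap confidence intervals, and a step-ahead transition forecasting
    experiment using random forests under repeated stratified
    cross-validation evaluated with Matthews' correlation coefficient and
    the corrected repeated k-fold CV t-test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
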