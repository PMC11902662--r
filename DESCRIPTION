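Package: skigears
Title: Cross-Country Ski Gear Classification from Instrumented Insoles
Version: 0.1.0
Authors@R:
    person("skigears", "developers", email = "skigears@example.org",
           role = c("aut", "cre"))
Description: Simulation, preprocessing and classification of cross-country
    skiing skating gears (G2R, G2L, G3) from instrumented-insole recordings
    (four plantar-pressure sensors plus a 9-DoF inertial measurement unit per
    foot, sampled at 100 Hz). Provides a synthetic gait-cycle signal
    generator with ground-truth gear labels, the full preprocessing chain
    (pressure offset removal, force-to-pressure conversion, gap cleaning,
    exponential moving-average smoothing, sliding-window segmentation with
    per-subframe median features, train-statistics normalization), a
    CNN-LSTM window classifier implemented in base R, the canonical set of
    23 pressure/inertial sensor-subset configurations, and a
    participant-grouped cross-validation and sensor-ablation harness with
    confusion matrices, per-class precision/recall/F1 and weighted average
    accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
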