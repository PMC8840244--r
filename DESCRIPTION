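Package: bpunet
Title: Cuffless Blood Pressure Estimation with a Shallow 1-D U-Net Feature
    Extractor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage cuffless blood-pressure estimation from
    photoplethysmogram (PPG) and electrocardiogram (ECG) waveforms. A
    signal-conditioning front end removes baseline wander by moving-minimum
    polynomial fitting, normalizes channels, derives velocity and
    acceleration PPG (VPG/APG), extracts per-segment systolic/diastolic
    labels, and rejects low-quality segments by peak statistics. A shallow
    one-dimensional U-Net autoencoder maps the predictor channels to the
    arterial blood pressure (ABP) waveform and exposes an in-line dense
    bottleneck as a learned feature extractor; classical regressors predict
    per-segment SBP/DBP from those features. Evaluation follows the field's
    standards: mean absolute error, British Hypertension Society grading,
    AAMI compliance, linear-fit and Pearson agreement, and Bland-Altman
    limits of agreement. A seeded synthetic waveform generator provides
    ground-truth-labelled PPG/ECG/ABP triplets so the full pipeline is
    testable without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    caret,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
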