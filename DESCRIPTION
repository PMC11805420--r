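Package: phenocast
Title: Forecasting Ordinal Mental-State Self-Reports from Passive Smartphone Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested benchmark pipeline for forecasting self-reported mental
    states from passive digital-phenotyping data. Generates synthetic cohorts
    with per-period smartphone sensing features and skewed 4-point ordinal
    self-reports, builds time-based train/validation/test splits with
    Yeo-Johnson standardization, trains gradient-boosted and recurrent
    forecasters on ordinal-regression and binary-classification tasks over
    three horizons, and evaluates them with class-imbalance-aware metrics
    (macro-averaged mean absolute error, balanced accuracy, scale-normalized
    balanced error) against Monte Carlo label-resampling baselines with
    Bonferroni-corrected significance calls and a cross-condition statistical
    battery (Wilcoxon, Friedman, Spearman).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
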