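Package: pgms
Title: Personalized Glucose Monitoring: Boosted Error Correction for
    Non-Invasive Blood Glucose Readings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Correction of non-invasive blood glucose readings by per-cluster
    error-prediction models. Paired invasive/non-invasive readings are split
    into six clinical glucose ranges (hypoglycemia through critically
    diabetic); within each range an AdaBoost.R2 regression ensemble with a
    learning-rate-modified weight update learns the additive difference
    between reference and sensor readings, and corrected values are obtained
    by a confidence-weighted median of the ensemble. Includes device-accuracy
    metrics (MARD, signed min/max error, RMSE, cluster-weighted aggregation),
    Clarke error grid analysis, a K-means clustering baseline, a calibrated
    synthetic generator of paired readings matching published summary
    statistics, and recalibration/personalization workflow helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rpart,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
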