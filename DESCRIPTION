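Package: moodcast
Title: Personalised Daily Depression Forecasting from Mobile Sensing and
    Momentary Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for personalised prediction and one-day-ahead
    forecasting of daily depressive-symptom scores (PHQ-2) from passive
    smartphone sensing and ecological momentary assessment. Provides a
    synthetic-cohort simulator with subject-heterogeneous latent severity
    trajectories and controllable missingness; extraction of 19 daily
    passive features (GPS mobility with significant-place clustering,
    communication, phone usage, sleep inference); data-quality filtering
    with weekly-mean imputation; a gated-recurrent-unit sequence regressor
    with three personalisation strategies (transfer learning with a shared
    backbone, sex subgroup models, subject-dependent standardisation);
    subject-dependent cross-validation; and group- and individual-level
    fairness indices for regression (sex fairness score and bias, Gini
    coefficient of per-subject error, distance-to-median indices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
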