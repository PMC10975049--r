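Package: dietresponder
Title: Inter-Individual Response Analysis for Crossover Dietary Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Characterises inter-individual variation in response to dietary
    interventions assessed in crossover randomised controlled trials.
    Computes percentage-change responses from baseline across vascular and
    cognitive endpoints, classifies participants into responder (RS),
    non-responder (NRS) and average groups by direction-aware quartile
    division, summarises response proportions, ranges and cross-arm
    consistency, and tests covariate associations with the response group.
    A metabolomics biomarker stage filters LC-MS feature tables by pooled-QC
    relative standard deviation and nonparametric variability, applies log
    transformation and autoscaling, and searches for discriminating features
    with univariate ROC curves and repeatedly subsampled random-forest
    classification models. A synthetic-data generator emulates the trial
    and feature-table structure so the whole pipeline is testable without
    access to participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
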