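Package: asdsurv
Title: Text-Based Case Classification for Autism Spectrum Disorder Surveillance
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies children in developmental-disability surveillance
    systems as meeting or not meeting the autism spectrum disorder (ASD)
    surveillance case definition, using only the free text of their
    developmental evaluations. Implements the full pipeline: aggregation of a
    child's evaluations into one document, Porter stemming, 1-3-gram
    extraction with a minimum document-frequency filter, TF-IDF weighting,
    random-forest classification with out-of-bag permutation-importance
    feature selection, and a vote-share cutoff calibrated to the training
    class prevalence. Includes a surveillance evaluation layer (agreement,
    sensitivity, specificity, predictive values, Cohen's kappa, rank-based
    ROC AUC, cutoff sweeps, prevalence estimation with confidence intervals,
    and concordance profiling) and a seeded synthetic-corpus generator with
    known ground truth for end-to-end validation without confidential
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    randomForest,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
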