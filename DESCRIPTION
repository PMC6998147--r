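Package: prfpipe
Title: Smoke-Exposure Biomarker Discovery and COPD Risk Scoring
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for deriving descriptive marker genes from in vitro
    smoke-exposure transcriptomics and converting their expression into an
    individual risk index for chronic obstructive pulmonary disease (COPD).
    Provides empirical-Bayes moderated t-tests with Benjamini-Hochberg false
    discovery rate control for differential expression, a deterministic
    direction-consistent intersection cascade that distils dose- and
    time-independent response genes into a marker panel, repeated stratified
    k-fold random-forest evaluation of panel classification accuracy, and a
    potential-risk-factor (PRF) index composed from two chained stepwise
    logistic models (non-smoker vs smoker, smoker vs COPD). Includes a
    synthetic-data generator with planted ground truth for exposure and
    cohort designs, the published reference model parameters, tidy() and
    glance() methods, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
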