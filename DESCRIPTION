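Package: soleposture
Title: Center-of-Pressure Posturography from Insole Plantar Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing wireless-insole plantar pressure recordings
    collected during static and active balance tasks. Computes per-foot
    center-of-pressure (COP) trajectories from 8-zone force data, extracts a
    60-measure posturography feature bank (positional, dynamic and spectral
    sway measures), combines features across feet into average and asymmetry
    summaries, and runs a selection-classification-interpretation stack:
    ANOVA F pre-filtering, forward sequential feature selection on
    cross-validated F1, five classifier families, stratified cross-validated
    evaluation with ROC averaging, common-feature and Shapley-value key
    feature identification. Includes a synthetic insole-pressure cohort
    generator with controllable group effects so the full pipeline can be
    exercised and validated without access to clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    e1071,
    randomForest,
    glmnet,
    class,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
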