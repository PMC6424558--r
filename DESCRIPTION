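Package: metabGA
Title: Metabolic Gestational Age Dating and External Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, model fitting and external validation tools for
    postnatal gestational age estimation from newborn screening dried-blood-spot
    metabolic profiles. Provides a seeded cohort simulator with Table-1-style
    clinical structure and gestational-age-dependent analyte signals,
    birthweight-for-gestational-age reference charts with SGA classification,
    sample screening and multiple imputation of missing analytes with pooled
    scoring, a three-model elastic-net hierarchy (clinical, analyte, full, with
    pairwise analyte interactions), and validation surfaces: RMSE,
    within-1/2-week accuracy, stratified reports, residual diagnostics,
    preterm ROC/AUC with DeLong confidence intervals, and calibration-slope
    recalibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
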