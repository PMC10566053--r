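Package: uroMetPanel
Title: Urine Metabolomic Marker Panels for Clinically Significant
    Prostate Cancer Risk Models
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for building and evaluating urine metabolomics risk
    models for clinically significant prostate cancer. Implements a
    resampling-stability marker-selection engine (repeated stratified
    K-fold logistic modelling with univariate screening, AIC backward
    elimination and multivariable pruning, followed by recurrence
    ranking and cumulative-AIC panel sizing), four NCCN-based endpoint
    definitions, and a clinical-utility evaluation layer: ROC/AUC with
    DeLong variance and paired AUC comparison, Youden and
    fixed-sensitivity operating points, enrollment-reweighted
    biopsy-avoidance estimates, and decision curve analysis. A
    synthetic-cohort generator reproduces the cohort structure the
    analysis assumes (risk-stratified subjects, right-skewed PSA,
    detection-limited GC-MS peak tables with planted marker effects) so
    the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
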