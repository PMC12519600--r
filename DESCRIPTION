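Package: cohortSPLS
Title: Sparse PLS-DA Biomarker Discovery for Binary Clinical Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end biomarker-discovery pipeline for case-control
    cohort tables with blocks of numeric predictors (cell percentages,
    serum proteins, gene expression, vascular and lifestyle measures) and
    a binary endpoint such as subclinical atherosclerotic plaque. Provides
    per-column imputation-method selection scored by univariate logistic
    AUC, Tukey-fence outlier detection with uniform-random replacement,
    two logarithmic variance-stabilising transforms, a Table-1 style
    univariate screen, a from-scratch sparse partial least squares
    discriminant analysis (sPLS-DA) with soft-thresholded loadings and
    three prediction distances, repeated stratified cross-validation with
    balanced-error-rate tuning of the number of retained variables and
    components, and a thresholded relevance network ranking the top
    predictors. A synthetic-cohort generator with a ground-truth manifest
    (planted effects, missing-at-random mask, injected outliers) makes
    every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
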