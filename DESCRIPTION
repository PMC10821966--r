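Package: fistulomics
Title: Multi-Omics, Multi-Volume Radiomics and Dosiomics Modelling of
    Radiotherapy-Induced Esophageal Fistula
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for predicting esophageal fistula in
    esophageal-cancer patients treated with intensity-modulated radiotherapy
    from planning CT and 3D dose distributions. Extracts radiomics features
    (first-order, 3D shape, texture over a Laplacian-of-Gaussian and
    stationary-wavelet filter bank with fixed-bin-number discretization) and
    dosiomics features (DVH Dx/Vx parameters, scale-invariant 3D dose
    moments, dose-based radiomics) over the esophagus, gross tumor volume
    and their union; selects features by resampling-frequency stability
    screening with Student t-tests and Pearson redundancy pruning; and
    evaluates L2-regularized logistic (ridge) classifiers under repeated
    stratified splits with DeLong/bootstrap confidence intervals, paired
    model comparison and decision-curve analysis. Includes a synthetic
    cohort generator with a stated logistic outcome model so the full study
    can be exercised without patient data, plus minimal NIfTI-1 volume I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
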