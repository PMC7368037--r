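Package: neurocca
Title: Sparse Canonical Correlation Modes Linking Functional Connectomes,
    Cognition and Ongoing Thought
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multivariate brain-behaviour association analysis:
    Fisher r-to-z connectome featurisation of ROI time series, robust
    (median-absolute-deviation) feature filtering, confound residualisation,
    an L1-penalised rank-1 matrix-decomposition solver for sparse canonical
    correlation analysis with deflation, cross-validated penalty selection,
    permutation-based family-wise inference on canonical modes, and Type III
    multivariate (Pillai's trace) regression relating neurocognitive mode
    scores to multi-dimensional experience-sampling reports.  A synthetic
    cohort generator with planted sparse cross-covariance modes supports
    validation of every stage against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    jsonlite,
    MASS,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
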