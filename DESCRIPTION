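Package: fcmvpa
Title: Functional Connectivity Features and Multivariate Pattern Analysis
    for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end resting-state fMRI functional-connectivity analysis:
    temporal preprocessing of BOLD series (volume discarding, detrending,
    band-pass filtering, Friston-24 motion and tissue-signal nuisance
    regression), three per-subject connectivity feature types (voxel-wise
    functional connectivity strength, atlas-based large-scale functional
    connectivity, regional homogeneity via Kendall's coefficient of
    concordance), stratified cross-validated linear support-vector-machine
    classification with train-only normalization and all-component PCA,
    permutation significance testing, discriminative weight mapping with
    cluster extraction, and mass-univariate group statistics with Monte-Carlo
    cluster-extent correction. Ships a synthetic-cohort generator with an
    injected, recoverable group effect so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
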