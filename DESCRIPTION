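Package: rsoda
Title: Statistical Object Distance Analysis for Two-Channel Nanoscopy Images
Version: 0.1.0
Authors@R:
    person("rsoda", "developers", email = "rsoda@example.org", role = c("aut", "cre"))
Description: Quantifies nanoscale spatial coupling between two channels of
    segmented fluorescent protein clusters in super-resolution (STED-class)
    images. Provides a-trous wavelet spot segmentation with morphological
    feature extraction, ring-binned Ripley statistics with boundary
    correction (statistical object distance analysis, SODA) yielding
    per-pair coupling probabilities and distances, permutation and
    chi-square population statistics, and unsupervised discovery of
    cluster subtypes from a 7-dimensional feature space via 2-D embedding,
    kernel density estimation and silhouette-selected hierarchical
    grouping. Includes a synthetic image generator with known ground truth
    for validation, minimal TIFF input/output, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Optional: python with umap-learn on the PATH for the
    UMAP embedding backend (a PCA backend is built in).
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
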