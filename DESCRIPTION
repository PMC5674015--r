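Package: histolearn
Title: Active Learning and Microvascular Phenotyping for Whole-Slide
    Histology Object Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for interactive classification of segmented
    histologic objects (cell nuclei) from precomputed feature tables.
    Implements an active-learning loop around a random-forest classifier with
    tree-vote-margin confidence, least-confident instance selection,
    per-slide labeling-priority heatmaps and AUC-tracked validation; plus two
    microvascular phenotype metrics: a clustering index (a modified Ripley's
    K statistic without density normalization or edge correction) and a
    hypertrophy index (principal-curve path-length scores summarized by
    negated skewness). Includes synthetic whole-slide simulators (clustered
    rare-positive point patterns, class-conditional feature distributions,
    latent morphologic continua) so the full workflow runs end-to-end
    without image data, and a command-line interface binding the pieces into
    a scriptable label-update-predict workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ranger,
    Rcpp,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    pROC
Config/testthat/edition: 3
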