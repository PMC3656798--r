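Package: hdpclust
Title: Hierarchical Dirichlet Process Clustering of Gene-Expression Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian nonparametric clustering of gene-expression matrices
    with a two-level hierarchical Dirichlet process (HDP) mixture. Inference
    uses a fully collapsed Chinese-restaurant-franchise Gibbs sampler with a
    conjugate Gaussian observation model (component means integrated out), in
    either exact categorical or Metropolis-Hastings-within-Gibbs mode. The
    package provides the fitting front end hdp_cluster(), posterior membership
    aggregation with canonical relabeling, MAP cluster assignment, clustering
    evaluation metrics (Rand index, silhouette index), synthetic-data
    generators for regulatory-network segmentation and time-course benchmark
    emulation, and plain-text expression-matrix input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
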