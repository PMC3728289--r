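Package: perturbLP
Title: Signed Signaling Network Inference from Perturbation Assays by
    Linear Programming
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs signed, directed protein signaling networks from
    (possibly combinatorial) RNAi knockdown assays. Observed protein
    activities are discretized against per-gene thresholds and a sparse
    edge-weight matrix is inferred by an L1-penalized linear program with
    slack variables that absorb measurement noise. Includes cross-validated
    selection of the slack penalty by prediction error, median/MAD edge
    summarization, bootstrap aggregation for replicate-rich data, a
    simulator for knockdown screens with a two-Gaussian measurement model,
    and ROC/PR/permutation-based benchmarking of inferred topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    boot,
    pracma,
    pROC,
    optparse
biocViews: NetworkInference, GraphAndNetwork, SystemsBiology, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
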