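Package: thermonet
Title: Protein-RNA Binding Prediction over Thermodynamic Structure Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts protein-RNA binding intensity by combining learned
    multi-length k-mer sequence embeddings with a thermodynamic ensemble of
    sampled RNA secondary structures. Structures are drawn from the Boltzmann
    distribution (a bundled partition-function sampler or an external
    RNAsubopt-compatible executable), annotated into paired / hairpin /
    internal-loop / multiloop / external contexts, and the most frequent
    structures feed rank-specific convolutional networks whose predictions
    are combined by Boltzmann-frequency weighting. Includes Huber-loss
    training with Adam, grid-search model selection, RNAcompete-style and
    CLIP-seq-style data handling, evaluation metrics, and a synthetic
    benchmark generator with planted sequence-only and hairpin-context
    binding signals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
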