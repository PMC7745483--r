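Package: emblink
Title: Graph-Embedding Ensembles for lncRNA-miRNA Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts lncRNA-miRNA interactions from sequences and known
    interactions. Builds a heterogeneous network combining k-mer-spectrum
    linear-neighborhood sequence similarity graphs with the bipartite
    interaction matrix, learns node representations with five graph-embedding
    algorithms (Laplacian eigenmaps, GraRep, HOPE, DeepWalk and a variational
    graph autoencoder), and combines them with two ensemble heads: stacked
    prediction integration (per-embedding random forests under a logistic
    meta-learner) and attention-based feature integration (a deep attention
    network that fuses embeddings into pair features scored by a random
    forest). Includes a synthetic planted-block data generator, a
    cross-validation and network-sparsity evaluation harness, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    glmnet,
    generics,
    jsonlite,
    Matrix,
    methods,
    purrr,
    ranger,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
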