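Package: pocketDTI
Title: Drug-Target Interaction Prediction on a Proteome-Wide
    Pocket-Similarity Knowledge Graph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a heterogeneous proteome-wide interaction graph from
    binding-pocket residue embeddings, drug embeddings, protein-protein
    interactions and known binding relationships, and predicts drug-target
    interactions by link prediction with a graph-transformer embedding trunk
    and a feedforward link head. Includes a drug-similarity split protocol
    with cluster-disjoint folds and message-passing leakage control, a
    proteome-wide scoring workflow for novel drugs, and a seeded synthetic
    data generator so the full pipeline can be exercised without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp,
    jsonlite,
    data.table,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
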