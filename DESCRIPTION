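Package: hyperMDA
Title: MiRNA-Disease Association Prediction by Hypergraph-Regularized
    Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate microRNA-disease associations from a binary
    association matrix, a precomputed miRNA functional-similarity matrix and
    disease term hierarchies. Gaussian interaction-profile kernels computed
    from the association matrix are fused with functional and semantic
    similarities; each miRNA-disease pair is represented by the concatenation
    of its miRNA and disease similarity rows; a k-nearest-neighbour hypergraph
    over training pairs supplies a Laplacian smoothness regularizer; and a
    projection from feature space to relevance scores is obtained in closed
    form from a hypergraph-regularized ridge objective. Includes leave-one-out
    and repeated k-fold cross-validation harnesses that zero held-out
    associations before kernel recomputation, a parameter sweep, a synthetic
    block-structured data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
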