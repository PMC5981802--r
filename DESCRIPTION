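Package: morphnet
Title: Individual Morphological Brain Networks from Multivariate
    Inter-Regional Distances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs single-subject morphological brain networks from
    vertex-wise cortical surface features by converting a multivariate
    (energy) Euclidean distance between the per-vertex feature
    distributions of two cortical regions into an edge similarity.
    Includes sparsity thresholding and small-world graph analysis against
    degree-preserving null networks, betweenness-centrality hub detection,
    one-way random-effects intraclass correlation for test-retest
    reliability, an edge-based Lasso + RBF-SVM leave-one-out
    classification pipeline with discriminative-edge aggregation and
    clinical-score correlation, five alternative single-feature
    edge-similarity formulas from the literature, and a seeded synthetic
    cohort generator emulating FreeSurfer-style surface exports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    glmnet,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
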