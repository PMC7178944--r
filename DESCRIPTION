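Package: gognn
Title: Dual Graph Convolutional Networks for Link Prediction on Graphs of Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Link prediction on two-level graphs of graphs, where each node of an
    external network (for example a drug-drug interaction network) is itself a
    labeled graph (a molecule). Implements a dual graph convolutional neural
    network trained end-to-end by backpropagation: an internal convolution over
    atoms with degree-specific weights produces compound vectors, an external
    convolution over the compound network refines them, and a symmetric two-layer
    predictor scores compound pairs. Includes classical similarity-index baselines
    (common neighbors, Jaccard, Katz), hashed circular fingerprints, a trainable
    relational-embedding baseline, negative sampling and imbalance-preserving
    splits, ROC/PR evaluation for imbalanced data, and a synthetic
    graph-of-graphs generator with planted internal motifs and external
    community structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    tibble,
    rlang,
    withr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
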