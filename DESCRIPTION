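Package: pairGBERT
Title: Protein-Protein Interaction Prediction with a Pair-Node Graph Transformer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions by casting each labelled
    protein pair as a node in a graph whose edges connect pairs sharing a
    protein, and classifying nodes with a from-scratch Graph-BERT: a
    PageRank-style intimacy matrix drives top-k linkless subgraph sampling,
    four additive input embeddings (projected raw features plus sinusoidal
    encodings of Weisfeiler-Lehman role codes, intimacy rank and hop
    distance) feed a multi-head transformer encoder with a graph-residual
    term, and fused subgraph representations pass through a softmax
    classifier. Includes full training machinery (Adam, binary
    cross-entropy, early stopping, stratified splits and k-fold
    cross-validation, MCC/F-score metrics, Welch's t-test), TSV/FASTA
    pipelines, and a synthetic-data generator with planted class signal so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
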