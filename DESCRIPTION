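Package: coresig
Title: Pairwise Expression Signatures, Core Modules, and Pathway
    Activity Scoring for Dendritic Cell Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing transcriptomes of related cell
    populations by pairwise differential expression.  Implements
    per-gene two-sample t-tests with fold-change gating, directional
    intersection of two signatures into a shared core module,
    bidirectional hierarchical clustering of the core-module submatrix,
    gene-set ("pathway") activity scoring from per-gene z-scores with
    square-root-of-set-size variance stabilisation, reference-anchored
    subset Z-scores, linear support-vector-machine ranking of
    discriminative pathways, a local hypergeometric over-representation
    test, and delta-delta-Ct relative quantification for qPCR
    validation.  A synthetic-data generator with planted ground truth
    (differential genes, a shared core module, and a coherently
    shifted pathway) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
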