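Package: mechmatch
Title: Enzyme Mechanism Classification by Template Matching on Binary
    Signature Matrices
Version: 1.0.0
Authors@R:
    person("mechmatch", "maintainers", email = "mechmatch@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing and exploiting the block structure of
    binary enzyme-by-signature annotation matrices. Implements a
    nearest-neighbour dictionary-search classifier with equal-distance
    ring voting and leave-one-out evaluation, algorithmic
    block-diagonalization of the annotation matrix with a diagonality
    score and presence/absence heatmap rendering, per-mechanism feature
    region extraction with sub-subspace (connected component) detection
    and pairwise Jaccard overlap reporting, a template library for
    exact or near-exact look-up of novel signature vectors, and a
    synthetic-data generator that plants near-disjoint per-label
    signature blocks, one completely overlapping label pair and one
    composite (union of sub-blocks) label. A subcommand-style command
    line interface covers simulation, evaluation, blockification,
    overlap reporting and prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
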