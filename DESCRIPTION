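Package: multicomm
Title: Multiplex Network Analysis of Cell-Cell Communication
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Represents ligand-receptor (and other interacting-pair)
    cell-cell communication results as layers of a multiplex network over
    cell types, quantifies pairwise layer dissimilarity with a weighted,
    directed, modified Jaccard measure, and uses it for unsupervised
    clustering of interacting pairs (average-linkage hierarchical
    clustering with a hybrid dynamic tree cut), supervised search for a
    user-specified communication pattern, and differential comparison of
    two biological conditions. Reads CellPhoneDB-style significant-means
    tables, per-pair weight matrices and a long edge-list format, and
    ships a synthetic-data generator with planted communication
    archetypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    pheatmap,
    yaml
Suggests:
    uwot,
    mclust,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
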