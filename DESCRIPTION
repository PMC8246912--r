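Package: lineagetrace
Title: Single-Cell Mapping of Basophil and Mast-Cell Differentiation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping hematopoietic lineage bifurcations
    at single-cell resolution, built around the basophil / mast-cell system.
    Implements flow-cytometry event preprocessing with diffusion-map and PCA
    embeddings plus cross-dataset projection; scRNA-seq normalisation,
    differential expression and cell-cycle scoring; PC1 and diffusion
    pseudotime ordering with sliding-window smoothing; a permutation test for
    genes dynamically expressed along pseudotime with Louvain clustering of
    their profiles; k-nearest-neighbor projection frequency scores;
    hypergeometric signature-overlap tests; colony fate classification from
    flow events; and a seeded synthetic-data generator producing bifurcating
    expression matrices, index-sort tables and flow event tables with ground
    truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
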