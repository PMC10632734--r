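Package: onionnet
Title: Onion Normalization and Integration of Gene Co-Essentiality Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds functional gene networks from gene-by-condition fitness
    matrices such as CRISPR dependency screens. Dominant low-dimensional
    signal (for example mitochondria-associated variation in dependency
    maps) is removed by classical PCA, robust PCA (principal component
    pursuit) or a 1D convolutional autoencoder; the residual "layers"
    obtained across a grid of hyperparameters are converted to Pearson
    similarity networks and fused into a single network by similarity
    network fusion ("onion" normalization). Includes a co-annotation
    benchmarking engine (precision versus true positives, contribution
    diversity, per-complex AUPRC, exclusion-list handling), top-edge
    network characterization, a cell-line tissue-of-origin k-nearest
    neighbour classifier, and a synthetic-data generator with planted
    confounders, complexes and tissue structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
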