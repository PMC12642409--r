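Package: synpid
Title: Synergy, Redundancy and Long-Range Correlations in Neural Population Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for spatially embedded binary neural activity
    rasters: hidden Markov binarization of deconvolved calcium traces,
    time-delayed mutual information and its partial information decomposition
    (minimum-mutual-information redundancy) for neuron pairs, null-model
    Z-scoring of the decomposition components matched on total information,
    correlation-length estimation from exponential decay of pairwise
    correlation with distance, effective information lengths, k-nearest-
    neighbour synergy and redundancy interaction layers with complementary /
    shared / unique shortest-path classification, and permutation-based group
    comparisons. Includes a dichotomized-Gaussian synthetic-data generator
    with known spatial correlation length and planted synergistic motifs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
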