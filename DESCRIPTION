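Package: lifnet
Title: Mean-Field Rates and Information Transfer of Degree-Correlated
    Leaky Integrate-and-Fire Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stationary firing rates of heterogeneous, degree-correlated
    networks of excitatory leaky integrate-and-fire neurons, computed from a
    k-population mean-field model: the network is partitioned into
    populations of equal in-degree and the coupled self-consistent rate
    equations, built on the Siegert first-passage transfer function and a
    joint degree distribution, are relaxed to their stable fixed point.
    Includes truncated power-law degree distributions, directed
    configuration-model generation with degree-preserving Metropolis
    rewiring towards assortative or disassortative in-degree correlations,
    a direct network simulator used as verification oracle, and the mutual
    information between sub-threshold stimuli and the noisy population-rate
    readout.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
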