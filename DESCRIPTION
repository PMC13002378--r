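Package: meanet
Title: Network Analysis of Multielectrode-Array Spike Recordings Under Paired Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sorted spike-train recordings from
    multielectrode arrays (MEAs) in paired experimental conditions
    (e.g. baseline versus an acute pharmacological treatment). Provides
    per-unit firing statistics, population-burst detection on summed
    rasters, K-means classification of putative pyramidal neurons and
    interneurons from waveform width and firing rate, cross-correlogram
    functional connectivity with significance thresholding, graph-theoretic
    and centrality metrics, small-world sigma and omega indices against
    degree-preserving random and lattice null ensembles, and a weighted
    spectral-scaling (Estrada index) classification of network topology
    into classes I-IV. A synthetic-data module generates paired-condition
    spike rasters with planted coupling, cell classes, rate changes and
    synchrony epochs so that every stage is testable without external
    recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
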