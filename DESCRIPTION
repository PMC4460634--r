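Package: grngpea
Title: Gene Regulatory Network Inference and Gene-Pair Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers gene regulatory networks from gene expression matrices with
    the BC3Net bootstrap ensemble over C3Net (mutual information estimated from
    the Pearson correlation), identifies significant functional, gene-family and
    genomic co-location subnetworks with a hypergeometric gene-pair enrichment
    analysis (GPEA), characterizes network structure (hubs, density, power-law
    degree exponent, shortest paths), and quantifies agreement between inferred
    and reference interaction networks (precision, recall, F-score, shared-edge
    tests, label-randomized baselines). Ships a synthetic-data generator that
    plants a scale-free dependency network in a Gaussian graphical model so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
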