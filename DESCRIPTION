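Package: dgrnet
Title: Differential Gene Regulatory Network Reconstruction and In
    Silico Perturbation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs phenotype-specific signed gene regulatory
    networks from a differential-expression contrast and a prior-knowledge
    interaction network, resolving unsigned interactions and pruning edges
    incompatible with the discretized expression program of each phenotype.
    Enumerates signed elementary circuits, identifies differential
    regulators, and ranks 1-4-gene clamped perturbations of the diseased
    network by how many gene states they revert to the healthy phenotype
    under synchronous Boolean dynamics. Includes differential-expression
    utilities (Welch test, Benjamini-Hochberg step-up, fold-change
    filtering), hypergeometric over-representation analysis against GMT
    gene-set collections, and a seeded synthetic-data generator with
    planted differentially expressed genes, signs, circuits and decoy
    edges for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
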