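Package: bandscan
Title: Cytogenetic Band Enrichment Scan for Disease-Associated Variants
Version: 0.1.0
Authors@R: person("Ahmad", "Rezai", email = "bandscan@example.org", role = c("aut", "cre"))
Description: Detects nonrandom clustering of disease-associated polymorphisms
    across cytogenetic bands with an exact Poisson rate-ratio F test,
    performs reciprocal hypergeometric over-representation analysis between
    gene sets and chromosomal bands, and runs a length-adjusted somatic
    mutation-burden analysis per band. Includes a synthetic-data module that
    emulates the GWAS variant point process, gene/mutation tables and gene
    sets so that every stage is testable without external downloads, and a
    command-line pipeline that orchestrates the full analysis from plain
    TSV/GMT inputs with Benjamini-Hochberg FDR control throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
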