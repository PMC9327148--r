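Package: sinescope
Title: Calibration and Regulatory Analysis of SINE Retrotransposon Families
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to calibrate the boundaries of short interspersed nuclear
    element (SINE) copies from target site duplications (TSD), split elements
    into head-body and poly(A) tail, and classify structural variants (tandem,
    nested, splice-shortened classes). Includes composition and CpG-island
    statistics, nucleotide diversity and molecular-clock divergence times,
    Needleman-Wunsch distance matrices with PCA embedding, a splice-signal
    enrichment analysis on consensus coordinates with a sampling-based
    hot-site threshold and a GT-AG excision model, and a paired-tissue
    differential-methylation and methylation-expression correlation pipeline.
    A synthetic-data module generates genomes with implanted elements,
    annotations, paired beta-binomial methylomes and coupled expression with
    full ground truth, so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    methods,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
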