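Package: grasfam
Title: Characterization of GRAS Transcription-Factor Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable workflow for the genome-wide characterization of
    GRAS transcription-factor gene families. Provides curated locus-table and
    GFF3 readers with exon/intron structure statistics, exact local protein
    alignment with Karlin-Altschul expectation values, reciprocal-best-hit
    orthology classification across genomes, neighbor-joining bootstrap
    consensus phylogenetics with reference-anchored subfamily assignment,
    catalog-based and de-novo conserved protein motif discovery, tandem and
    segmental duplication classification, expression-atlas tissue attribution
    with strict-threshold co-expression clustering, and a seeded synthetic
    gene-family generator with ground-truth labels so every stage can be
    exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
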