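Package: rnaisafe
Title: Transcriptome-Based Risk Assessment of dsRNA Off-Target Effects
    in Non-Target Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for judging whether an insecticidal double-stranded RNA
    (dsRNA) expressed by an RNAi crop perturbs the transcriptome of a
    non-target organism. Implements transcriptome-wide scanning for the
    longest contiguous exact match between each transcript and either
    strand of the dsRNA, a negative-binomial Wald test for differential
    expression with Benjamini-Hochberg correction, attribution of
    differentially expressed genes to target-gene homologs (local
    alignment with Karlin-Altschul E-values), KEGG pathway proximity
    levels, and contiguous-match classes, hypergeometric gene-set
    over-representation, and Shannon transcriptomic entropy as a
    homeostasis metric. A seeded synthetic-data generator with recorded
    ground truth makes every stage verifiable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
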