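Package: codonpop
Title: Codon Usage Bias Metrics and Alignment-Free Population Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes six families of codon-usage-bias metrics from coding
    sequences (codon frequency, codon aversion, identical codon pairing
    within a ribosomal window, co-tRNA codon pairing, ramp-sequence
    detection from relative synonymous codon usage, and nucleotide
    composition), population-level statistics over per-individual metric
    values (one-way ANOVA, Bonferroni thresholds, pairwise t-tests,
    Cohen's d, Tukey HSD, minor-allele frequencies), and alignment-free
    population identification from codon-pairing or codon-aversion motif
    sets via Jaccard distances and neighbor-joining, scored by percent
    predictive accuracy. Includes a synthetic-cohort simulator with
    controllable synonymous-codon divergence, planted ramp sequences and
    genotype tables so every pipeline stage is testable without external
    data.
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
    Matrix,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
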