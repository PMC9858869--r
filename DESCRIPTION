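Package: divergescan
Title: Divergence Landscapes and Demographic Model Selection for Speciation Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing genomic divergence between a pair of
    hybridizing or recently separated lineages from SNP data: folded joint
    site-frequency-spectrum construction with hypergeometric down-projection,
    coalescent-based composite-likelihood comparison of five divergence/gene-flow
    demographic models (strict isolation, isolation with migration, ancient
    migration, secondary contact, and secondary contact with a recent stop of
    gene flow), sliding-window Weir-Cockerham FST, nucleotide diversity and
    pixy-style dxy landscapes with outlier-window detection, fully diagnostic
    SNP discovery, Hill-Weir linkage-disequilibrium decay fitting, variant
    effect classification against gene models, and Fisher-exact GO term
    enrichment. Includes a seeded coalescent simulator that generates complete
    synthetic studies (all-sites VCF, reference FASTA, GFF3, GO map, population
    map) with optional barrier regions of locally suppressed gene flow and
    recombination, so every estimator can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stringr,
    jsonlite,
    yaml,
    generics,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    minpack.lm,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
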