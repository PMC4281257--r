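Package: methexpr
Title: Integrative Methylome and Transcriptome Analysis of Clonal Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrative analysis of methyl-CpG enrichment (MBD pull-down)
    sequencing and suppression-subtractive-hybridization (SSH) transcriptome
    libraries from two clonal variants. Places methyl-enriched reads on
    genome scaffolds with all-hits near-exact matching and multiplicity
    accounting, stratifies hits by genomic feature class (gene bodies,
    promoters, transposons and their flanks), calibrates SSH read counts
    against internal-control contig pairs, classifies per-gene differential
    expression and methylation, computes hypergeometric GO-term enrichment
    over the ontology DAG, and quantifies methylation-expression concordance
    per scaffold. Includes a synthetic-data generator with planted,
    machine-readable truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
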