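# Small shared fixtures built in code.

tiny_config <- function(seed = 42, ...) {
  base <- list(
    seed = seed, n_scaffolds = 4L, scaffold_length = 20000L,
    n_genes_per_scaffold = 3L, n_transposons_per_scaffold = 2L,
    reads_per_variant = 5000L, control_contig_count = 10L,
    go_term_count = 30L, planted_enriched_terms = 2L,
    repeat_copy_numbers = c(1L, 2L, 5L))
  over <- list(...)
  base[names(over)] <- over
  do.call(synthetic_config, base)
}

tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_genome(tiny_config())
    cache
  }
})

# hand-built 5-term DAG: r <- a <- b, r <- c, b and c both parents of d
toy_dag <- function() {
  go_dag(
    terms = tibble::tibble(
      term_id = c("GO:r", "GO:a", "GO:b", "GO:c", "GO:d"),
      name = c("root", "a", "b", "c", "d"),
      namespace = "molecular_function"),
    parents = tibble::tibble(
      term_id = c("GO:a", "GO:b", "GO:c", "GO:d", "GO:d"),
      parent_id = c("GO:r", "GO:a", "GO:r", "GO:b", "GO:c")))
}

make_reads <- function(seqs, variant = "orange", copy_count = 1L,
                       prefix = "r") {
  tibble::tibble(
    read_id = sprintf("%s%03d", prefix, seq_along(seqs)),
    sequence = seqs, variant = variant,
    copy_count = rep_len(copy_count, length(seqs)))
}
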