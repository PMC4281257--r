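test_that("concordance counts inverse methylation/expression pairs", {
  ranks <- tibble::tibble(
    scaffold_id = c("sA", "sB", "sC"),
    hits_orange = c(10, 30, 5), hits_green = c(30, 10, 5),
    length = 1000, density = c(3, 2, 1) / 100, rank = 1:3)
  genes <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                          scaffold_id = c("sA", "sB", "sC"))
  expr <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    orange = c(20, 0, 0), green = c(0, 20, 0), class = "x")
  # sA: meth up green, expr down green -> concordant; sB mirror -> concordant
  one <- concordance(ranks, expr, genes, top_k = 1)
  expect_equal(one$fraction, 1)
  both <- concordance(ranks, expr, genes, top_k = 2)
  expect_equal(both$fraction, 1)
  # sC is expression-silent: excluded from the denominator, reported apart
  all3 <- concordance(ranks, expr, genes, top_k = 3)
  expect_equal(all3$n_silent, 1)
  expect_equal(all3$n_evaluated, 2)
  expect_equal(all3$fraction, 1)
  expect_error(concordance(ranks, expr, genes, top_k = 0), "positive")
  expect_error(concordance(ranks, expr, genes, top_k = 9), "exceeds")
})

test_that("independently assigned directions give chance-level concordance", {
  set.seed(51)
  n <- 1000
  ranks <- tibble::tibble(
    scaffold_id = sprintf("s%04d", 1:n),
    hits_orange = rpois(n, 50), hits_green = rpois(n, 50),
    length = 1000)
  ranks$density <- (ranks$hits_orange + ranks$hits_green) / 2000
  ranks <- dplyr::arrange(ranks, dplyr::desc(density), scaffold_id)
  ranks$rank <- seq_len(n)
  genes <- tibble::tibble(gene_id = sprintf("g%04d", 1:n),
                          scaffold_id = ranks$scaffold_id)
  expr <- tibble::tibble(
    gene_id = genes$gene_id,
    orange = rpois(n, 10) + 1, green = rpois(n, 10) + 1, class = "x")
  cc <- concordance(ranks, expr, genes, top_k = n)
  expect_gt(cc$fraction, 0.4)
  expect_lt(cc$fraction, 0.6)
})

test_that("track export is deterministic and BED placements round-trip", {
  b <- tiny_bundle()
  reads <- dplyr::bind_rows(simulate_methylome_reads(b, "orange"),
                            simulate_methylome_reads(b, "green"))
  pl <- place_reads(reads[1:200, ], b$scaffolds)
  contigs <- tibble::tibble(
    contig_id = "c1", variant = "green", sequence = "ACGT", read_count = 3L,
    gene_id = "g", status = "assigned", scaffold_id = names(b$scaffolds)[1],
    locus_start = 10L, locus_end = 14L, score = 4)
  hits <- per_scaffold_hits(pl, reads, names(b$scaffolds))
  ranks <- rank_scaffolds(hits, b$scaffold_lengths)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  export_tracks(pl, reads, contigs, ranks, dir1)
  export_tracks(pl, reads, contigs, ranks, dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
  # BED round-trip preserves the placement set
  bed <- read_bed(file.path(dir1, "methylation_orange.bed"))
  orange_pl <- pl[pl$read_id %in% reads$read_id[reads$variant == "orange"], ]
  expect_setequal(paste(bed$scaffold_id, bed$start, bed$end, bed$strand),
                  paste(orange_pl$scaffold_id, orange_pl$start,
                        orange_pl$end, orange_pl$strand))
  # empty placements still produce a valid (commented) file
  dir3 <- withr::local_tempdir()
  export_tracks(pl[0, ], reads, contigs, ranks, dir3)
  expect_true(startsWith(readLines(file.path(dir3,
                                             "methylation_orange.bed"))[1],
                         "#"))
})

test_that("the pipeline runs from a file manifest and validates it", {
  b <- tiny_bundle()
  dir <- withr::local_tempdir()
  write_genome_bundle(b, dir)
  ro <- simulate_methylome_reads(b, "orange")
  rg <- simulate_methylome_reads(b, "green")
  ssh <- simulate_ssh_libraries(b)
  write_reads_fasta(ro, file.path(dir, "ro.fa"), file.path(dir, "ro.tsv"))
  write_reads_fasta(rg, file.path(dir, "rg.fa"), file.path(dir, "rg.tsv"))
  write_reads_fasta(ssh$orange, file.path(dir, "co.fa"),
                    file.path(dir, "co.tsv"), count_col = "read_count")
  write_reads_fasta(ssh$green, file.path(dir, "cg.fa"),
                    file.path(dir, "cg.tsv"), count_col = "read_count")
  manifest <- list(
    scaffolds = file.path(dir, "scaffolds.fa"),
    genes = file.path(dir, "genes.gff3"),
    transposons = file.path(dir, "transposons.bed"),
    annotations = file.path(dir, "annotations.tsv"),
    go_dag = file.path(dir, "go.obo"),
    reads_orange = file.path(dir, "ro.fa"),
    counts_orange = file.path(dir, "ro.tsv"),
    reads_green = file.path(dir, "rg.fa"),
    counts_green = file.path(dir, "rg.tsv"),
    contigs_orange = file.path(dir, "co.fa"),
    contig_counts_orange = file.path(dir, "co.tsv"),
    contigs_green = file.path(dir, "cg.fa"),
    contig_counts_green = file.path(dir, "cg.tsv"))
  res_files <- suppressMessages(suppressWarnings(
    run_pipeline(manifest = manifest)))
  res_mem <- suppressMessages(suppressWarnings(run_pipeline(b)))
  expect_equal(nrow(res_files$placements), nrow(res_mem$placements))
  expect_equal(res_files$calibration$scale_factor,
               res_mem$calibration$scale_factor)
  # missing input -> abort naming it
  expect_error(run_pipeline(manifest = manifest[-5]), "go_dag")
})

test_that("two pipeline runs over the same bundle are identical", {
  b <- tiny_bundle()
  r1 <- suppressMessages(suppressWarnings(run_pipeline(b)))
  r2 <- suppressMessages(suppressWarnings(run_pipeline(b)))
  expect_identical(r1$placements, r2$placements)
  expect_identical(r1$expression, r2$expression)
  expect_identical(r1$enrichment$p_value, r2$enrichment$p_value)
  expect_identical(r1$concordance, r2$concordance)
  # summary numbers are re-derivable from stage outputs
  hw <- tidyr::pivot_wider(r1$scaffold_hits, names_from = "variant",
                           values_from = "hits", names_prefix = "hits_")
  expect_equal(r1$scaffold_correlation,
               pearson_correlation(hw$hits_orange, hw$hits_green))
  expect_equal(sum(r1$reads$copy_count),
               2 * b$config$reads_per_variant)
})

test_that("pipeline config rejects unknown options and keeps defaults", {
  cfg <- pipeline_config()
  expect_equal(cfg$mismatch_fraction, 0.04)
  expect_equal(cfg$strong_min, 20)
  expect_equal(cfg$slight_min, 5)
  expect_equal(cfg$top_k, c(500, 10000))
  cfg2 <- pipeline_config(alpha = 0.1)
  expect_equal(cfg2$alpha, 0.1)
  expect_error(pipeline_config(bogus = 1), "unknown pipeline option")
})

test_that("plot helpers return ggplot objects", {
  b <- tiny_bundle()
  reads <- simulate_methylome_reads(b, "orange")[1:100, ]
  pl <- place_reads(reads, b$scaffolds)
  spec <- multiplicity_spectrum(pl, reads)
  expect_s3_class(plot_multiplicity_spectrum(spec), "ggplot")
  hits <- per_scaffold_hits(pl, reads, names(b$scaffolds))
  hits2 <- dplyr::bind_rows(hits,
                            dplyr::mutate(hits, variant = "green",
                                          hits = hits + 1))
  expect_s3_class(plot_scaffold_hits(hits2), "ggplot")
})
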