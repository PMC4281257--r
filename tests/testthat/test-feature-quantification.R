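simple_annotation <- function() {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"), scaffold_id = "s",
    start = c(5000L, 20000L), end = c(9000L, 24000L),
    strand = c("+", "-"))
  exons <- tibble::tibble(
    gene_id = c("gA", "gA", "gB", "gB"), scaffold_id = "s",
    start = c(5000L, 8000L, 20000L, 23000L),
    end = c(6000L, 9000L, 21000L, 24000L),
    strand = rep(c("+", "-"), each = 2), exon_number = c(1L, 2L, 1L, 2L))
  te <- tibble::tibble(te_id = "t1", scaffold_id = "s",
                       start = 10000L, end = 12000L)
  list(genes = genes, exons = exons, te = te,
       lens = c(s = 100000L))
}

test_that("promoter windows are strand-aware and measured from the TSS", {
  a <- simple_annotation()
  idx <- build_region_index(a$genes, a$exons, a$te, a$lens)
  p1 <- idx[idx$class == "promoter_0_2kb" & idx$feature_id == "gA", ]
  expect_equal(c(p1$start, p1$end), c(3000L, 5000L))
  p2 <- idx[idx$class == "promoter_2_3kb" & idx$feature_id == "gA", ]
  expect_equal(c(p2$start, p2$end), c(2000L, 3000L))
  # minus-strand gene: upstream lies to the right of the gene end
  m1 <- idx[idx$class == "promoter_0_2kb" & idx$feature_id == "gB", ]
  expect_equal(c(m1$start, m1$end), c(24000L, 26000L))
})

test_that("transposon border and distal windows are placed and clipped", {
  a <- simple_annotation()
  idx <- build_region_index(a$genes, a$exons, a$te, a$lens)
  border <- idx[idx$class == "transposon_border_1kb", ]
  expect_equal(nrow(border), 2)
  expect_setequal(paste(border$start, border$end),
                  c("9000 10000", "12000 13000"))
  distal <- idx[idx$class == "transposon_upstream_49_51kb", ]
  # strandless: left of the leftmost coordinate, clipped at the scaffold edge
  expect_equal(nrow(distal), 0)  # 10 kb - 51 kb < 0 and 10 kb - 49 kb < 0

  te2 <- tibble::tibble(te_id = "t2", scaffold_id = "s",
                        start = 60000L, end = 61000L)
  idx2 <- build_region_index(a$genes, a$exons, te2, a$lens)
  d2 <- idx2[idx2$class == "transposon_upstream_49_51kb", ]
  expect_equal(c(d2$start, d2$end), c(9000L, 11000L))
  # no emitted interval may exceed scaffold bounds
  expect_true(all(idx2$start >= 0 & idx2$end <= a$lens))
})

test_that("introns complement exons inside the gene body", {
  a <- simple_annotation()
  idx <- build_region_index(a$genes, a$exons, a$te, a$lens)
  intr <- idx[idx$class == "intron" & idx$feature_id == "gA", ]
  expect_equal(c(intr$start, intr$end), c(6000L, 8000L))
  for (g in c("gA", "gB")) {
    ex_w <- sum(with(idx[idx$class == "exon" & idx$feature_id == g, ],
                     end - start))
    in_w <- sum(with(idx[idx$class == "intron" & idx$feature_id == g, ],
                     end - start))
    body <- idx[idx$class == "gene_body" & idx$feature_id == g, ]
    expect_equal(ex_w + in_w, body$end - body$start)
  }
  # a gene without exon records degrades to single-exon with a warning
  expect_warning(
    idx3 <- build_region_index(a$genes, a$exons[a$exons$gene_id != "gB", ],
                               a$te, a$lens),
    "without exons")
  expect_equal(nrow(idx3[idx3$class == "intron" & idx3$feature_id == "gB", ]), 0)
})

test_that("region counting applies the 1 bp overlap rule per class", {
  a <- simple_annotation()
  idx <- build_region_index(a$genes, a$exons, a$te, a$lens)
  pl <- tibble::tibble(
    read_id = c("in_exon", "junction", "desert"),
    scaffold_id = "s",
    start = c(5100L, 5980L, 40000L),
    end = c(5150L, 6020L, 40050L),
    strand = "+", mismatches = 0L)
  reads <- tibble::tibble(read_id = pl$read_id, sequence = "A",
                          variant = "orange", copy_count = c(1L, 2L, 1L))
  counts <- count_by_region(pl, idx, reads)
  cell <- function(f, cl) {
    h <- counts$hits[counts$feature_id == f & counts$class == cl]
    if (length(h) == 0) 0 else h
  }
  # read inside an exon: exon + gene_body, not intron
  # junction read (copy 2): exon + intron + gene_body
  expect_equal(cell("gA", "exon"), 1 + 2)
  expect_equal(cell("gA", "intron"), 2)
  expect_equal(cell("gA", "gene_body"), 3)
  # the desert read increments nothing
  expect_false("desert" %in% counts$feature_id)
})

test_that("region counting equals the quadratic brute-force oracle", {
  set.seed(11)
  for (rep in 1:3) {
    idx <- tibble::tibble(
      scaffold_id = sample(c("s1", "s2"), 60, TRUE),
      start = sample(0:900, 60, TRUE))
    idx$end <- idx$start + sample(10:120, 60, TRUE)
    idx$class <- sample(c("gene_body", "exon", "promoter_0_2kb"), 60, TRUE)
    idx$feature_id <- sample(sprintf("f%d", 1:8), 60, TRUE)
    idx$strand <- "+"
    pl <- tibble::tibble(
      read_id = sprintf("r%03d", 1:40),
      scaffold_id = sample(c("s1", "s2"), 40, TRUE),
      start = sample(0:980, 40, TRUE))
    pl$end <- pl$start + sample(20:40, 40, TRUE)
    pl$strand <- "+"; pl$mismatches <- 0L
    reads <- tibble::tibble(read_id = pl$read_id, sequence = "A",
                            variant = sample(c("orange", "green"), 40, TRUE),
                            copy_count = sample(1:4, 40, TRUE))
    got <- count_by_region(pl, idx, reads) %>%
      dplyr::arrange(feature_id, class, variant)
    want <- oracle_count_by_region(pl, idx, reads)
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("gene methylation classes honour fold, floor and zero-denominator rules", {
  counts <- tibble::tibble(
    feature_id = rep(c("g1", "g2", "g3", "g4"), each = 2),
    class = "gene_body",
    variant = rep(c("orange", "green"), 4),
    hits = c(10, 20,   10, 19,   0, 6,   1, 2))
  rec <- classify_gene_methylation(counts, fold = 2, min_hits = 5)
  got <- setNames(rec$class, rec$gene_id)
  expect_equal(got[["g1"]], "up2x_green")    # boundary 2x included
  expect_equal(got[["g2"]], "unchanged")
  expect_equal(got[["g3"]], "up2x_green")    # zero denominator, 6 >= min_hits
  expect_equal(got[["g4"]], "insufficient")  # max < min_hits
  expect_error(classify_gene_methylation(counts, fold = 1), "fold")
})

test_that("scaffold ranking is by density with id tie-break", {
  hits <- tibble::tibble(
    scaffold_id = rep(c("sA", "sB", "sC"), each = 2),
    variant = rep(c("orange", "green"), 3),
    hits = c(10, 20,  15, 15,  5, 5))
  lens <- c(sA = 10000L, sB = 10000L, sC = 1000L)
  r <- rank_scaffolds(hits, lens)
  expect_equal(r$density[r$scaffold_id == "sA"], 0.0015)
  # sC density (5/1000) wins; sA and sB tie at 0.0015 -> id order
  expect_equal(r$scaffold_id[order(r$rank)], c("sC", "sA", "sB"))
  expect_error(rank_scaffolds(hits, c(sA = 0L, sB = 1L, sC = 1L)), "zero-length")

  # doubling both variants cannot lower the rank
  hits2 <- hits
  hits2$hits[hits2$scaffold_id == "sA"] <- hits2$hits[hits2$scaffold_id == "sA"] * 2
  r2 <- rank_scaffolds(hits2, lens)
  expect_lte(r2$rank[r2$scaffold_id == "sA"], r$rank[r$scaffold_id == "sA"])
})

test_that("planted methylation shifts are recovered on synthetic data", {
  b <- generate_genome(tiny_config(seed = 21, n_scaffolds = 8L,
                                   shared_hotspot_fraction = 0.3,
                                   reads_per_variant = 50000L))
  reads <- dplyr::bind_rows(simulate_methylome_reads(b, "orange"),
                            simulate_methylome_reads(b, "green"))
  pl <- place_reads(reads, b$scaffolds)
  idx <- build_region_index(b$genes, b$exons, b$transposons,
                            b$scaffold_lengths)
  counts <- count_by_region(pl, idx, reads)
  rec <- classify_gene_methylation(counts, fold = 2, min_hits = 5)

  # expected per-variant gene-body hits implied by the planted fragment
  # weights: condition, as the recovery property does, on a true expected
  # fold >= 2 and expected hits >= 4 x min_hits
  frag <- msei_fragments(b$scaffolds)
  frag <- frag[frag$end - frag$start >= b$config$min_fragment_length, ]
  hs <- b$truth$hotspots
  wt <- function(variant) {
    w <- rep(1, nrow(frag))
    h <- hs[hs$variant %in% c("both", variant), ]
    for (i in seq_len(nrow(h))) {
      w[frag$scaffold_id == h$scaffold_id[i] & frag$start < h$end[i] &
          frag$end > h$start[i]] <- b$config$fragment_capture_bias
    }
    w * b$config$reads_per_variant / sum(w)
  }
  eo <- wt("orange"); eg <- wt("green")
  exp_hits <- function(g, ev) {
    gene <- b$genes[b$genes$gene_id == g, ]
    sum(ev[frag$scaffold_id == gene$scaffold_id & frag$start < gene$end &
             frag$end > gene$start])
  }
  shift <- b$truth$methylation_shift %>%
    dplyr::filter(.data$region == "gene_body") %>%
    dplyr::distinct(.data$gene_id, .data$direction) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::filter(dplyr::n() == 1) %>%
    dplyr::ungroup()
  shift$e_orange <- vapply(shift$gene_id, exp_hits, 0, ev = eo)
  shift$e_green <- vapply(shift$gene_id, exp_hits, 0, ev = eg)
  eligible <- shift %>%
    dplyr::filter(pmax(.data$e_orange, .data$e_green) >= 20,
                  pmax(.data$e_orange / .data$e_green,
                       .data$e_green / .data$e_orange) >= 2)
  expect_gte(nrow(eligible), 5)
  joined <- dplyr::inner_join(eligible, rec[rec$region == "gene_body", ],
                              by = "gene_id")
  expected <- ifelse(joined$direction == "green", "up2x_green",
                     "down2x_green")
  expect_gte(mean(joined$class == expected), 0.9)
})
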