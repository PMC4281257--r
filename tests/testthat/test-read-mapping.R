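test_that("place_reads finds every copy of a planted repeat", {
  set.seed(1)
  scfs <- random_scaffolds(3, 4000)
  unit <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                collapse = "")
  # plant 50 copies at disjoint positions across the scaffolds
  pos <- seq(0, 3900, by = 78)[1:50]
  scf_of <- rep(names(scfs), length.out = 50)
  for (i in 1:50) {
    s <- scf_of[i]
    substr(scfs[[s]], pos[i] + 1, pos[i] + 30) <- unit
  }
  pl <- place_reads(make_reads(unit), scfs, mismatch_fraction = 0)
  expect_gte(nrow(pl), 50)  # chance extra hits possible but not expected
  planted <- paste(scf_of, pos)
  found <- paste(pl$scaffold_id, pl$start)
  expect_true(all(planted %in% found))
  # and the brute-force oracle agrees exactly
  expect_equal(as.data.frame(pl),
               oracle_place_reads(make_reads(unit), scfs, 0))
})

test_that("reverse-complement reads place on the minus strand", {
  set.seed(2)
  scfs <- random_scaffolds(1, 500)
  locus <- substring(scfs[[1]], 101, 140)
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(locus, "")[[1]]), collapse = ""))
  pl <- place_reads(make_reads(rc), scfs, mismatch_fraction = 0)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$start, 100)
  expect_equal(pl$strand, "-")

  # symmetry: rev-complementing every read flips strands, same locations
  reads <- make_reads(c(locus, rc), prefix = "q")
  fwd <- place_reads(reads, scfs)
  reads_rc <- reads
  reads_rc$sequence <- vapply(reads$sequence, function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = "")), "")
  rev <- place_reads(reads_rc, scfs)
  key <- function(d) sort(paste(d$scaffold_id, d$start, d$read_id))
  expect_identical(key(fwd), key(rev))
  expect_identical(sort(paste(fwd$read_id, fwd$start, fwd$strand)),
                   sort(paste(rev$read_id, rev$start,
                              ifelse(rev$strand == "+", "-", "+"))))
})

test_that("the 4% cutoff admits floor(0.04 * length) mismatches and no more", {
  base <- paste(rep(c("ACGTG"), 20), collapse = "")  # 100 bp backbone
  read <- substring(base, 11, 35)                    # 25 bp -> 1 mismatch allowed
  one_mm <- read
  substr(one_mm, 5, 5) <- if (substring(one_mm, 5, 5) == "A") "C" else "A"
  two_mm <- one_mm
  substr(two_mm, 15, 15) <- if (substring(two_mm, 15, 15) == "A") "C" else "A"
  scfs <- c(s1 = paste0("TTTTTTTTTT", one_mm, "TTTTTTTTTT"),
            s2 = paste0("TTTTTTTTTT", two_mm, "TTTTTTTTTT"))
  pl <- place_reads(make_reads(read), scfs, mismatch_fraction = 0.04)
  expect_equal(pl$scaffold_id, "s1")
  expect_equal(pl$mismatches, 1)
})

test_that("reads with excess ambiguity are skipped with a warning", {
  scfs <- random_scaffolds(1, 200)
  reads <- make_reads(c(paste(rep("N", 30), collapse = ""),
                        substring(scfs[[1]], 1, 30)))
  expect_warning(pl <- place_reads(reads, scfs), ">10% N")
  expect_false("r001" %in% pl$read_id)
  expect_true("r002" %in% pl$read_id)
})

test_that("placement set shrinks monotonically as the cutoff tightens", {
  set.seed(3)
  scfs <- random_scaffolds(2, 2000)
  reads <- make_reads(vapply(1:10, function(i) {
    at <- sample(1950, 1)
    s <- substring(scfs[[sample(2, 1)]], at, at + sample(20:50, 1))
    # corrupt one base half the time
    if (i %% 2) substr(s, 3, 3) <- "A"
    s
  }, ""))
  key <- function(d) paste(d$read_id, d$scaffold_id, d$start, d$strand)
  prev <- NULL
  for (frac in c(0.1, 0.04, 0)) {
    pl <- place_reads(reads, scfs, mismatch_fraction = frac)
    if (!is.null(prev)) expect_true(all(key(pl) %in% prev))
    prev <- key(pl)
  }
})

test_that("multiplicity spectrum recovers planted location counts", {
  set.seed(4)
  scf <- random_scaffolds(1, 12000)
  # plant: 100 unique reads, 10 reads at 2 copies, 1 read at 50 copies
  mk_unit <- function() paste(sample(c("A", "C", "G", "T"), 24, TRUE),
                              collapse = "")
  slots <- sample(seq(0, 11976, by = 24))  # disjoint 24-bp slots
  si <- 1
  put <- function(unit) {
    at <- slots[si]; si <<- si + 1
    substr(scf[[1]], at + 1, at + 24) <<- unit
  }
  uniq <- replicate(100, mk_unit()); for (u in uniq) put(u)
  dbl <- replicate(10, mk_unit()); for (u in dbl) { put(u); put(u) }
  rep50 <- mk_unit(); for (i in 1:50) put(rep50)
  reads <- make_reads(c(uniq, dbl, rep50))
  pl <- place_reads(reads, scf, mismatch_fraction = 0)
  spec <- multiplicity_spectrum(pl, reads)
  got <- setNames(spec$n_reads, spec$n_locations)
  expect_equal(got[["1"]], 100)
  expect_equal(got[["2"]], 10)
  expect_equal(got[["50"]], 1)
  # conservation: sum over bins of bin x reads = total placements
  expect_equal(sum(spec$n_locations * spec$n_reads), nrow(pl))
})

test_that("spectrum reports unplaced reads in bin 0 and handles empty input", {
  scfs <- random_scaffolds(1, 300)
  reads <- make_reads(paste(rep("ACGT", 10), collapse = ""))
  pl <- place_reads(reads, scfs)
  spec <- multiplicity_spectrum(pl, reads)
  if (nrow(pl) == 0) expect_equal(spec$n_locations, 0L)
  empty <- multiplicity_spectrum(empty <- place_reads(make_reads(character()),
                                                      scfs),
                                 make_reads(character()))
  expect_equal(nrow(empty), 0)
})

test_that("occurrence classes follow the copy-count rule", {
  o <- make_reads(c("AAAA", "CCCC", "GGGG", "TTTT"), "orange",
                  copy_count = c(0L, 1L, 6L, 7L))[-1, ]
  g <- make_reads(c("AAAA", "CCCC", "GGGG"), "green",
                  copy_count = c(2L, 1L, 7L))
  cl <- occurrence_classes(o, g, t = 2)
  got <- setNames(cl$class, cl$sequence)
  expect_equal(got[["AAAA"]], "only_green")    # (green 2, orange 0)
  expect_equal(got[["CCCC"]], "once_each")     # (1, 1)
  expect_equal(got[["GGGG"]], "shared")        # (7, 6)
  expect_equal(got[["TTTT"]], "only_orange")   # (0, 7)

  # t = 5 with "shared" requiring both to satisfy the rule
  cl5 <- occurrence_classes(o, g, t = 5)
  got5 <- setNames(cl5$class, cl5$sequence)
  expect_equal(got5[["GGGG"]], "shared")
  # strict reading: > t (green 7 > 5 and orange 6 > 5)
  clgt <- occurrence_classes(o, g, t = 5, comparison = "gt")
  expect_equal(setNames(clgt$class, clgt$sequence)[["GGGG"]], "shared")
  # at > 6 the orange side (6) no longer qualifies
  clgt6 <- occurrence_classes(o, g, t = 6, comparison = "gt")
  expect_equal(setNames(clgt6$class, clgt6$sequence)[["GGGG"]], "other")
  tab <- occurrence_class_table(cl)
  expect_equal(sum(tab$n), 4)
})

test_that("per-scaffold hits weight placements by copy count", {
  scfs <- random_scaffolds(2, 1000)
  locus <- substring(scfs[[1]], 101, 130)
  substr(scfs[[1]], 501, 530) <- locus  # same read twice on scaffold 1
  reads <- make_reads(locus, copy_count = 3L)
  pl <- place_reads(reads, scfs, mismatch_fraction = 0)
  hits <- per_scaffold_hits(pl, reads, names(scfs))
  expect_equal(hits$hits[hits$scaffold_id == "s01"], 6)  # 2 placements x 3
  expect_equal(hits$hits[hits$scaffold_id == "s02"], 0)
})

test_that("pearson_correlation handles identities and degenerate inputs", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x + 3), -1)
  expect_message(r <- pearson_correlation(rep(1, 5), x), "constant")
  expect_true(is.na(r))
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
  set.seed(5)
  a <- rpois(1000, 20); b <- rpois(1000, 20)
  expect_lt(abs(pearson_correlation(a, b)), 0.1)
})
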