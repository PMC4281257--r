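# Independent oracles, deliberately naive: pure-R exhaustive computations
# against which the package's optimized implementations are checked.

# all-positions, both-strand Hamming scan; returns the same columns as
# place_reads() for one read sequence
oracle_place_one <- function(sequence, scaffolds, mismatch_fraction) {
  L <- nchar(sequence)
  max_mm <- floor(mismatch_fraction * L)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(sequence, "")[[1]]),
                                     collapse = ""))
  out <- list()
  for (scf in names(scaffolds)) {
    s <- strsplit(scaffolds[[scf]], "")[[1]]
    SL <- length(s)
    if (SL < L) next
    for (query in list(c(sequence, "+"), c(rc, "-"))) {
      q <- strsplit(query[1], "")[[1]]
      for (p in 0:(SL - L)) {
        mm <- sum(s[(p + 1):(p + L)] != q | q == "N")
        if (mm <= max_mm) {
          out[[length(out) + 1]] <- data.frame(
            scaffold_id = scf, start = p, end = p + L,
            strand = query[2], mismatches = mm)
        }
      }
    }
  }
  do.call(rbind, out)
}

oracle_place_reads <- function(reads, scaffolds, mismatch_fraction) {
  out <- list()
  for (i in seq_len(nrow(reads))) {
    hits <- oracle_place_one(reads$sequence[i], scaffolds, mismatch_fraction)
    if (!is.null(hits)) {
      hits$read_id <- reads$read_id[i]
      out[[length(out) + 1]] <- hits
    }
  }
  d <- do.call(rbind, out)
  if (is.null(d)) return(d)
  d <- d[order(d$scaffold_id, d$start, d$read_id, d$strand),
         c("read_id", "scaffold_id", "start", "end", "strand", "mismatches")]
  rownames(d) <- NULL
  d
}

# quadratic brute-force region counting with the same increment rule as
# count_by_region(): one increment per (placement, feature, class) with any
# >= 1 bp overlap, weighted by copy count
oracle_count_by_region <- function(placements, index, reads) {
  if (!"variant" %in% names(reads)) reads$variant <- "all"
  pl <- merge(placements, reads[, c("read_id", "variant", "copy_count")],
              by = "read_id")
  acc <- list()
  for (i in seq_len(nrow(pl))) {
    seen <- character()
    for (j in seq_len(nrow(index))) {
      if (pl$scaffold_id[i] != index$scaffold_id[j]) next
      if (pl$start[i] < index$end[j] && pl$end[i] > index$start[j]) {
        key <- paste(index$feature_id[j], index$class[j])
        if (key %in% seen) next
        seen <- c(seen, key)
        k2 <- paste(key, pl$variant[i])
        acc[[k2]] <- (acc[[k2]] %||% 0) + pl$copy_count[i]
      }
    }
  }
  if (length(acc) == 0) {
    return(data.frame(feature_id = character(), class = character(),
                      variant = character(), hits = numeric()))
  }
  parts <- do.call(rbind, strsplit(names(acc), " "))
  d <- data.frame(feature_id = parts[, 1], class = parts[, 2],
                  variant = parts[, 3], hits = unlist(acc))
  d <- d[order(d$feature_id, d$class, d$variant), ]
  rownames(d) <- NULL
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive-enumeration hypergeometric upper tail: draw every size-n subset
# of 1:N (first m elements carry the term) and count overlaps >= k
oracle_hyper_tail <- function(N, m, n, k) {
  if (n == 0 || k == 0) return(1)
  subsets <- utils::combn(N, n)
  overlaps <- colSums(subsets <= m)
  mean(overlaps >= k)
}

random_scaffolds <- function(n, len, gc = 0.4) {
  s <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, "")
  stats::setNames(s, sprintf("s%02d", seq_len(n)))
}
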