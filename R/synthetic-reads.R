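#' MseI restriction fragments of a scaffold set
#'
#' MseI recognises TTAA and cuts between the first T and TAA, so a site at
#' 0-based position p splits the sequence after p + 1. Fragments tile each
#' scaffold exactly: they are non-overlapping, ordered, and concatenate to
#' the original sequence.
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @return Tibble with `scaffold_id`, `start`, `end` (0-based half-open) and
#'   `sequence`.
#' @export
msei_fragments <- function(scaffolds) {
  out <- lapply(names(scaffolds), function(s) {
    seq <- scaffolds[[s]]
    sites <- Biostrings::start(
      Biostrings::matchPattern("TTAA", Biostrings::DNAString(seq))) - 1L
    if (length(sites) == 0) {
      warning("scaffold ", s, " has no TTAA site; emitting it whole",
              call. = FALSE)
      cuts <- integer()
    } else {
      cuts <- sites + 1L  # cut T^TAA
    }
    b <- c(0L, cuts, nchar(seq))
    tibble(scaffold_id = s, start = b[-length(b)], end = b[-1])
  })
  frag <- dplyr::bind_rows(out)
  frag$sequence <- unname(substring(scaffolds[frag$scaffold_id],
                                    frag$start + 1, frag$end))
  frag
}

#' Simulate MBD-captured methylome reads for one variant
#'
#' Fragments every scaffold at MseI sites, drops fragments shorter than
#' `config$min_fragment_length`, assigns each remaining fragment sampling
#' weight 1 — multiplied by `fragment_capture_bias` when the fragment
#' overlaps a methylation hot spot active in this variant — and draws
#' `reads_per_variant` read copies from the resulting multinomial. Each
#' sampled fragment is emitted once, on a random strand, with its draw as
#' the copy count, mirroring how identical pyrosequencing reads collapse to
#' one distinct sequence plus a multiplicity.
#'
#' @param bundle A [generate_genome()] bundle.
#' @param variant `"orange"` or `"green"`.
#' @param seed Integer seed (default derived from the bundle's config).
#' @return Tibble of reads: `read_id`, `sequence`, `variant`, `copy_count`,
#'   plus the source coordinates `scaffold_id`, `start`, `end`, `strand`.
#' @export
simulate_methylome_reads <- function(bundle, variant = c("orange", "green"),
                                     seed = NULL) {
  variant <- match.arg(variant)
  config <- bundle$config
  seed <- seed %||% derive_seed(config$seed, paste0("methylome_", variant))
  set.seed(seed)
  frag <- msei_fragments(bundle$scaffolds)
  frag <- frag[frag$end - frag$start >= config$min_fragment_length, ]

  hs <- bundle$truth$hotspots
  hs <- hs[hs$variant %in% c("both", variant), ]
  w <- rep(1, nrow(frag))
  if (nrow(hs) > 0) {
    ov <- interval_overlaps(frag, hs)
    w[unique(ov$query)] <- config$fragment_capture_bias
  }
  counts <- as.vector(stats::rmultinom(1, config$reads_per_variant, w))
  keep <- counts > 0
  frag <- frag[keep, ]
  counts <- counts[keep]
  strand <- sample(c("+", "-"), nrow(frag), replace = TRUE)
  seqs <- frag$sequence
  flip <- strand == "-"
  if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
  tibble(
    read_id = sprintf("%s_read_%05d", variant, seq_len(nrow(frag))),
    sequence = seqs, variant = variant, copy_count = counts,
    scaffold_id = frag$scaffold_id, start = frag$start, end = frag$end,
    strand = strand)
}

# 0-based half-open overlap join between two interval tibbles sharing
# scaffold_id; returns row indices (query, subject)
interval_overlaps <- function(query, subject) {
  lv <- union(unique(query$scaffold_id), unique(subject$scaffold_id))
  q <- GenomicRanges::GRanges(factor(query$scaffold_id, levels = lv),
                              IRanges::IRanges(query$start + 1, query$end))
  s <- GenomicRanges::GRanges(factor(subject$scaffold_id, levels = lv),
                              IRanges::IRanges(subject$start + 1, subject$end))
  hits <- GenomicRanges::findOverlaps(q, s)
  tibble(query = S4Vectors::queryHits(hits),
         subject = S4Vectors::subjectHits(hits))
}
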