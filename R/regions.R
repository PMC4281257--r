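# Region stratification of the genome and hit quantification per class.

REGION_CLASSES <- c("gene_body", "exon", "intron", "promoter_0_2kb",
                    "promoter_2_3kb", "transposon_body",
                    "transposon_border_1kb", "transposon_upstream_49_51kb")

#' Build the genomic region index
#'
#' Eight interval classes, each interval carrying its owning feature id:
#' gene bodies, exons, introns (gene body minus exons), the two strand-aware
#' promoter windows (0-2 kb and 2-3 kb upstream of the transcription start),
#' transposon bodies, their 1 kb borders (upstream plus downstream flank),
#' and a distal 49-51 kb upstream control window. Transposons typically lack
#' strand, in which case "upstream" means left of the leftmost coordinate.
#' All intervals are clipped at scaffold edges.
#'
#' @param genes,exons Gene model tibbles (0-based half-open) as produced by
#'   [generate_genome()] or [read_genes_gff3()].
#' @param transposons Tibble with `te_id`, `scaffold_id`, `start`, `end`,
#'   optionally `strand`.
#' @param scaffold_lengths Named integer vector.
#' @param promoter_kb,promoter2_kb,border_kb,distal_kb Window sizes in kb
#'   (defaults 2, 3, 1 and c(49, 51)).
#' @return Tibble (`region_index`): `scaffold_id`, `start`, `end`, `class`,
#'   `feature_id`, `strand`.
#' @export
build_region_index <- function(genes, exons, transposons, scaffold_lengths,
                               promoter_kb = 2, promoter2_kb = 3,
                               border_kb = 1, distal_kb = c(49, 51)) {
  p1 <- as.integer(promoter_kb * 1000)
  p2 <- as.integer(promoter2_kb * 1000)
  bb <- as.integer(border_kb * 1000)
  d1 <- as.integer(distal_kb[1] * 1000)
  d2 <- as.integer(distal_kb[2] * 1000)
  pieces <- list()

  if (nrow(genes) > 0) {
    pieces$gene_body <- genes %>%
      dplyr::transmute(.data$scaffold_id, .data$start, .data$end,
                       class = "gene_body", feature_id = .data$gene_id,
                       .data$strand)
    ex <- exons
    if (nrow(ex) == 0 || !all(genes$gene_id %in% ex$gene_id)) {
      missing <- setdiff(genes$gene_id, ex$gene_id)
      if (length(missing) > 0) {
        warning(length(missing), " gene(s) without exons treated as ",
                "single-exon", call. = FALSE)
        ex <- dplyr::bind_rows(ex, genes %>%
          dplyr::filter(.data$gene_id %in% missing) %>%
          dplyr::mutate(exon_number = 1L))
      }
    }
    pieces$exon <- ex %>%
      dplyr::transmute(.data$scaffold_id, .data$start, .data$end,
                       class = "exon", feature_id = .data$gene_id, .data$strand)
    pieces$intron <- compute_introns(genes, ex)
    tss_up <- function(from_kb, to_kb) {
      genes %>% dplyr::transmute(
        .data$scaffold_id,
        wstart = ifelse(.data$strand == "-", .data$end + from_kb,
                        .data$start - to_kb),
        wend = ifelse(.data$strand == "-", .data$end + to_kb,
                      .data$start - from_kb),
        feature_id = .data$gene_id, .data$strand) %>%
        dplyr::rename(start = "wstart", end = "wend")
    }
    pieces$promoter_0_2kb <- tss_up(0L, p1) %>%
      dplyr::mutate(class = "promoter_0_2kb")
    pieces$promoter_2_3kb <- tss_up(p1, p2) %>%
      dplyr::mutate(class = "promoter_2_3kb")
  }

  if (nrow(transposons) > 0) {
    te <- transposons
    if (!"strand" %in% names(te)) te$strand <- "."
    pieces$transposon_body <- te %>%
      dplyr::transmute(.data$scaffold_id, .data$start, .data$end,
                       class = "transposon_body", feature_id = .data$te_id,
                       .data$strand)
    pieces$transposon_border_1kb <- dplyr::bind_rows(
      te %>% dplyr::transmute(.data$scaffold_id, wstart = .data$start - bb,
                              wend = .data$start, feature_id = .data$te_id,
                              .data$strand),
      te %>% dplyr::transmute(.data$scaffold_id, wstart = .data$end,
                              wend = .data$end + bb, feature_id = .data$te_id,
                              .data$strand)) %>%
      dplyr::rename(start = "wstart", end = "wend") %>%
      dplyr::mutate(class = "transposon_border_1kb")
    pieces$transposon_upstream_49_51kb <- te %>%
      dplyr::transmute(
        .data$scaffold_id,
        wstart = ifelse(.data$strand == "-", .data$end + d1,
                        .data$start - d2),
        wend = ifelse(.data$strand == "-", .data$end + d2,
                      .data$start - d1),
        feature_id = .data$te_id, .data$strand) %>%
      dplyr::rename(start = "wstart", end = "wend") %>%
      dplyr::mutate(class = "transposon_upstream_49_51kb")
  }

  idx <- dplyr::bind_rows(pieces)
  if (nrow(idx) == 0) {
    return(tibble(scaffold_id = character(), start = integer(),
                  end = integer(), class = character(),
                  feature_id = character(), strand = character()))
  }
  # clip at scaffold bounds; drop intervals that fall entirely outside
  lens <- scaffold_lengths[idx$scaffold_id]
  clipped <- idx$start < 0 | idx$end > lens
  if (any(clipped & idx$class %in% c("gene_body", "exon", "transposon_body"))) {
    warning("feature(s) extending past scaffold end clipped", call. = FALSE)
  }
  idx$start <- pmax(idx$start, 0L)
  idx$end <- pmin(idx$end, unname(lens))
  idx <- idx[idx$start < idx$end, ]
  idx %>%
    dplyr::select("scaffold_id", "start", "end", "class", "feature_id",
                  "strand") %>%
    dplyr::arrange(.data$class, .data$scaffold_id, .data$start,
                   .data$feature_id)
}

# introns = gene body minus exons, per gene
compute_introns <- function(genes, exons) {
  out <- exons %>%
    dplyr::group_by(.data$gene_id, .data$scaffold_id, .data$strand) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::reframe(istart = .data$end[-dplyr::n()],
                   iend = .data$start[-1]) %>%
    dplyr::filter(.data$istart < .data$iend)
  out %>% dplyr::transmute(.data$scaffold_id, start = .data$istart,
                           end = .data$iend, class = "intron",
                           feature_id = .data$gene_id, .data$strand)
}

#' Count placement hits per (feature, class, variant)
#'
#' A placement increments a (feature, class) cell by its read's copy count
#' when it overlaps any interval of that feature and class by at least 1 bp.
#' Classes are counted independently: one placement may increment several
#' classes (a read straddling an exon/intron junction counts in both, and in
#' the gene body).
#'
#' @param placements Output of [place_reads()].
#' @param index A region index from [build_region_index()].
#' @param reads Read tibble carrying `copy_count` and `variant`.
#' @return Tibble (`region_counts`): `feature_id`, `class`, `variant`,
#'   `hits`.
#' @export
count_by_region <- function(placements, index, reads) {
  if (!"variant" %in% names(reads)) reads$variant <- "all"
  pl <- placements %>%
    dplyr::inner_join(reads[, c("read_id", "variant", "copy_count")],
                      by = "read_id")
  if (nrow(pl) == 0 || nrow(index) == 0) {
    return(tibble(feature_id = character(), class = character(),
                  variant = character(), hits = numeric()))
  }
  ov <- interval_overlaps(pl, index)
  tibble(variant = pl$variant[ov$query],
         copy_count = pl$copy_count[ov$query],
         placement = ov$query,
         feature_id = index$feature_id[ov$subject],
         class = index$class[ov$subject]) %>%
    dplyr::distinct(.data$placement, .data$feature_id, .data$class,
                    .keep_all = TRUE) %>%
    dplyr::group_by(.data$feature_id, .data$class, .data$variant) %>%
    dplyr::summarise(hits = sum(.data$copy_count), .groups = "drop")
}

#' Class totals of a region count table
#' @param counts Output of [count_by_region()].
#' @return Tibble with `class`, `variant`, `hits`.
#' @export
region_class_totals <- function(counts) {
  counts %>%
    dplyr::group_by(.data$class, .data$variant) %>%
    dplyr::summarise(hits = sum(.data$hits), .groups = "drop")
}

#' Classify per-gene methylation fold change between variants
#'
#' For the gene body and the 0-2 kb promoter, each gene is classified from
#' its copy-weighted hit counts: `insufficient` when the larger count is
#' below `min_hits`, `up2x_green` when green >= fold x orange (boundary
#' included: green = 2 x orange is a two-fold increase), `down2x_green` for
#' the mirror case, `unchanged` otherwise. A zero denominator takes the
#' direction of the non-zero side when that side reaches `min_hits`.
#'
#' @param counts Output of [count_by_region()].
#' @param fold Fold threshold (> 1, default 2).
#' @param min_hits Minimum hits for a confident call (default 5).
#' @return Tibble: `gene_id`, `region`, `hits_orange`, `hits_green`, `class`.
#' @export
classify_gene_methylation <- function(counts, fold = 2, min_hits = 5) {
  if (fold <= 1) stop("`fold` must be > 1", call. = FALSE)
  wide <- counts %>%
    dplyr::filter(.data$class %in% c("gene_body", "promoter_0_2kb")) %>%
    tidyr::pivot_wider(names_from = "variant", values_from = "hits",
                       values_fill = 0) %>%
    dplyr::rename(region = "class", gene_id = "feature_id")
  for (v in c("orange", "green")) if (!v %in% names(wide)) wide[[v]] <- 0
  wide %>%
    dplyr::mutate(hits_orange = .data$orange, hits_green = .data$green) %>%
    dplyr::transmute(
      .data$gene_id, .data$region, .data$hits_orange, .data$hits_green,
      class = dplyr::case_when(
        pmax(hits_orange, hits_green) < min_hits ~ "insufficient",
        hits_green >= fold * hits_orange ~ "up2x_green",
        hits_orange >= fold * hits_green ~ "down2x_green",
        TRUE ~ "unchanged"))
}

#' Rank scaffolds by methylation density
#'
#' Density is the arithmetic mean of the two variants' hit totals divided by
#' scaffold length; scaffolds are ranked by density, descending, ties broken
#' by scaffold id.
#'
#' @param hits Output of [per_scaffold_hits()] over both variants.
#' @param scaffold_lengths Named integer vector.
#' @return Tibble: `scaffold_id`, `hits_orange`, `hits_green`, `length`,
#'   `density`, `rank`.
#' @export
rank_scaffolds <- function(hits, scaffold_lengths) {
  if (any(scaffold_lengths <= 0)) stop("zero-length scaffold", call. = FALSE)
  hits %>%
    tidyr::pivot_wider(names_from = "variant", values_from = "hits",
                       names_prefix = "hits_", values_fill = 0) %>%
    dplyr::mutate(length = unname(scaffold_lengths[.data$scaffold_id]),
                  density = (.data$hits_orange + .data$hits_green) / 2 /
                    .data$length) %>%
    dplyr::arrange(dplyr::desc(.data$density), .data$scaffold_id) %>%
    dplyr::mutate(rank = dplyr::row_number())
}
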