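# Read placement and multiplicity statistics.

#' Place methyl reads on scaffolds (all hits, both strands)
#'
#' Reports every genomic location on either strand where a read matches with
#' Hamming distance at most `floor(mismatch_fraction * read length)`. No
#' best-hit selection is performed: multi-mapping reads keep all their
#' locations, which is what the downstream multiplicity and per-scaffold
#' statistics rely on. Matching is indel-free; the engine uses a pigeonhole
#' seed index but reproduces an exhaustive scan exactly.
#'
#' @param reads Tibble with `read_id`, `sequence` and optionally `variant`,
#'   `copy_count`. Reads with more than 10% ambiguous bases (N) are skipped
#'   with a warning; remaining Ns never match any base.
#' @param scaffolds Named character vector of scaffold sequences.
#' @param mismatch_fraction Allowed mismatch fraction in `[0, 0.1]`
#'   (default 0.04, the conventional read-mapper cutoff).
#' @return Tibble of placements: `read_id`, `scaffold_id`, `start` (0-based),
#'   `end` (exclusive), `strand`, `mismatches`.
#' @export
place_reads <- function(reads, scaffolds, mismatch_fraction = 0.04) {
  stopifnot(is.character(scaffolds), !is.null(names(scaffolds)))
  if (!is.numeric(mismatch_fraction) || mismatch_fraction < 0 ||
      mismatch_fraction > 0.1) {
    stop("`mismatch_fraction` must be in [0, 0.1]", call. = FALSE)
  }
  if (nrow(reads) == 0) return(empty_placements())
  n_frac <- stringr::str_count(reads$sequence, "[^ACGTacgt]") /
    nchar(reads$sequence)
  skip <- n_frac > 0.1
  if (any(skip)) {
    warning(sum(skip), " read(s) with >10% N skipped: ",
            paste(utils::head(reads$read_id[skip], 5), collapse = ", "),
            call. = FALSE)
    reads <- reads[!skip, , drop = FALSE]
  }
  if (nrow(reads) == 0) return(empty_placements())
  max_mm <- as.integer(floor(mismatch_fraction * nchar(reads$sequence)))
  hits <- cpp_place_reads(unname(scaffolds), reads$sequence, max_mm)
  tibble(
    read_id = reads$read_id[hits$query],
    scaffold_id = names(scaffolds)[hits$scaffold],
    start = hits$start,
    end = hits$start + nchar(reads$sequence)[hits$query],
    strand = ifelse(hits$strand > 0, "+", "-"),
    mismatches = hits$mismatches) %>%
    dplyr::arrange(.data$scaffold_id, .data$start, .data$read_id, .data$strand)
}

empty_placements <- function() {
  tibble(read_id = character(), scaffold_id = character(), start = integer(),
         end = integer(), strand = character(), mismatches = integer())
}

#' Multiplicity spectrum: genomic locations per distinct read
#'
#' For each distinct read the number of genomic locations it occupies is
#' counted (reads placed nowhere land in bin 0); the spectrum is the
#' per-variant histogram of those counts.
#'
#' @param placements Output of [place_reads()].
#' @param reads The read tibble given to [place_reads()] (defines the
#'   universe of distinct reads, including unplaced ones).
#' @return Tibble with `variant`, `n_locations`, `n_reads`.
#' @export
multiplicity_spectrum <- function(placements, reads) {
  if (!"variant" %in% names(reads)) reads$variant <- "all"
  per_read <- placements %>%
    dplyr::count(.data$read_id, name = "n_locations")
  reads %>%
    dplyr::left_join(per_read, by = "read_id") %>%
    dplyr::mutate(n_locations = dplyr::coalesce(.data$n_locations, 0L)) %>%
    dplyr::count(.data$variant, .data$n_locations, name = "n_reads") %>%
    dplyr::arrange(.data$variant, .data$n_locations)
}

#' Cross-variant occurrence classes of distinct sequences
#'
#' Matches identical sequences across the two variants' read sets and
#' classifies each distinct sequence at a copy-count threshold `t`:
#' `shared` when both variants satisfy the count rule, `only_green` /
#' `only_orange` when one side satisfies it and the other has count 0,
#' `once_each` when both sides have exactly one copy, `other` otherwise.
#'
#' @param reads_orange,reads_green Read tibbles with `sequence`,
#'   `copy_count`.
#' @param t Copy-count threshold (>= 1).
#' @param comparison `"ge"` (count >= t, default) or `"gt"` (count > t);
#'   both readings of "represented more than t times" are supported.
#' @return Tibble with one row per distinct sequence: `sequence`,
#'   `count_orange`, `count_green`, `class`.
#' @export
occurrence_classes <- function(reads_orange, reads_green, t = 2L,
                               comparison = c("ge", "gt")) {
  comparison <- match.arg(comparison)
  stopifnot(t >= 1)
  rule <- if (comparison == "ge") function(x) x >= t else function(x) x > t
  o <- reads_orange %>% dplyr::group_by(.data$sequence) %>%
    dplyr::summarise(count_orange = sum(.data$copy_count), .groups = "drop")
  g <- reads_green %>% dplyr::group_by(.data$sequence) %>%
    dplyr::summarise(count_green = sum(.data$copy_count), .groups = "drop")
  dplyr::full_join(o, g, by = "sequence") %>%
    dplyr::mutate(
      count_orange = dplyr::coalesce(.data$count_orange, 0L),
      count_green = dplyr::coalesce(.data$count_green, 0L),
      class = dplyr::case_when(
        rule(count_orange) & rule(count_green) ~ "shared",
        rule(count_green) & count_orange == 0 ~ "only_green",
        rule(count_orange) & count_green == 0 ~ "only_orange",
        count_orange == 1 & count_green == 1 ~ "once_each",
        TRUE ~ "other"))
}

#' Tally an occurrence-class table
#' @param classes Output of [occurrence_classes()].
#' @return Tibble with `class`, `n`.
#' @export
occurrence_class_table <- function(classes) {
  dplyr::count(classes, .data$class, name = "n")
}

#' Copy-count-weighted hits per scaffold
#'
#' A hit is one placement weighted by its read's copy count (one distinct
#' read sequenced c times that maps to two locations contributes 2c hits).
#'
#' @param placements Output of [place_reads()].
#' @param reads Read tibble carrying `copy_count` (and `variant`).
#' @param scaffold_ids Character vector defining the full scaffold universe
#'   (scaffolds without hits are reported with 0).
#' @return Tibble with `scaffold_id`, `variant`, `hits`.
#' @export
per_scaffold_hits <- function(placements, reads,
                              scaffold_ids = unique(placements$scaffold_id)) {
  if (!"variant" %in% names(reads)) reads$variant <- "all"
  variants <- unique(reads$variant)
  counts <- placements %>%
    dplyr::inner_join(reads[, c("read_id", "variant", "copy_count")],
                      by = "read_id") %>%
    dplyr::group_by(.data$scaffold_id, .data$variant) %>%
    dplyr::summarise(hits = sum(.data$copy_count), .groups = "drop")
  tidyr::expand_grid(scaffold_id = scaffold_ids, variant = variants) %>%
    dplyr::left_join(counts, by = c("scaffold_id", "variant")) %>%
    dplyr::mutate(hits = dplyr::coalesce(.data$hits, 0))
}

#' Pearson correlation with explicit degenerate handling
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return The Pearson coefficient, or `NA` (with a message) when either
#'   vector is constant, for which the coefficient is undefined.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("correlation undefined for a constant vector; returning NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}
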