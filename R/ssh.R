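# SSH transcriptome: contig-to-gene assignment, internal-control
# calibration, and per-gene differential expression classes.

#' Assign SSH contigs to genes via near-exact genome alignment
#'
#' Each contig is matched against the genome on both strands (indel-free,
#' up to `max_mismatch_frac` mismatches) and scored as
#' `length - 3 * mismatches` (+1 per match, -2 per mismatch), so a 100-bp
#' exact match scores 100 while anything below ~75% identity never reaches
#' a positive score. The unique best-scoring locus at or above `min_score`
#' is kept; contigs with tied best loci are flagged ambiguous and left
#' unassigned, as are contigs without an acceptable locus. The retained
#' locus is assigned to the gene whose body or 0-2 kb promoter overlaps it
#' (largest overlap wins; an exact tie leaves the contig unassigned).
#'
#' @param contigs Tibble with `contig_id`, `variant`, `sequence`,
#'   `read_count`.
#' @param scaffolds Named character vector.
#' @param genes Gene tibble (0-based half-open, with `strand`).
#' @param min_score Minimum alignment score (default 60).
#' @param max_mismatch_frac Mismatch budget of the matcher (default 0.05).
#' @return `contigs` with added `gene_id` (NA when unassigned), `score`,
#'   `status` in assigned / unassigned / ambiguous, and locus columns
#'   `scaffold_id`, `locus_start`, `locus_end`.
#' @export
assign_contigs <- function(contigs, scaffolds, genes, min_score = 60,
                           max_mismatch_frac = 0.05) {
  if (nrow(contigs) == 0) stop("no contigs supplied", call. = FALSE)
  max_mm <- as.integer(floor(max_mismatch_frac * nchar(contigs$sequence)))
  hits <- cpp_place_reads(unname(scaffolds), contigs$sequence, max_mm)
  hits$score <- nchar(contigs$sequence)[hits$query] - 3L * hits$mismatches
  hits <- hits[hits$score >= min_score, , drop = FALSE]

  out <- contigs
  out$gene_id <- NA_character_
  out$score <- NA_real_
  out$status <- "unassigned"
  out$scaffold_id <- NA_character_
  out$locus_start <- NA_integer_
  out$locus_end <- NA_integer_
  if (nrow(hits) == 0) return(tibble::as_tibble(out))

  # gene bodies + promoters as assignment targets
  targets <- dplyr::bind_rows(
    genes %>% dplyr::transmute(.data$scaffold_id, .data$start, .data$end,
                               gene_id = .data$gene_id),
    genes %>% dplyr::transmute(
      .data$scaffold_id,
      wstart = ifelse(.data$strand == "-", .data$end, .data$start - 2000L),
      wend = ifelse(.data$strand == "-", .data$end + 2000L, .data$start),
      gene_id = .data$gene_id) %>%
      dplyr::rename(start = "wstart", end = "wend") %>%
      dplyr::filter(.data$start < .data$end))

  for (i in seq_len(nrow(contigs))) {
    h <- hits[hits$query == i, , drop = FALSE]
    if (nrow(h) == 0) next
    best <- max(h$score)
    hb <- h[h$score == best, , drop = FALSE]
    loci <- unique(hb[, c("scaffold", "start")])
    if (nrow(loci) > 1) { out$status[i] <- "ambiguous"; next }
    scf <- names(scaffolds)[hb$scaffold[1]]
    st <- hb$start[1]; en <- st + nchar(contigs$sequence[i])
    out$score[i] <- best
    out$scaffold_id[i] <- scf
    out$locus_start[i] <- st
    out$locus_end[i] <- en
    tg <- targets[targets$scaffold_id == scf & targets$start < en &
                    targets$end > st, , drop = FALSE]
    if (nrow(tg) == 0) next
    ovl <- pmin(tg$end, en) - pmax(tg$start, st)
    per_gene <- tapply(ovl, tg$gene_id, sum)
    top <- per_gene[per_gene == max(per_gene)]
    if (length(top) > 1) { out$status[i] <- "ambiguous"; next }
    out$gene_id[i] <- names(top)
    out$status[i] <- "assigned"
  }
  n_un <- sum(out$status != "assigned")
  if (n_un > 0) {
    message(n_un, " of ", nrow(out), " contig(s) left unassigned (",
            sum(out$status == "ambiguous"), " ambiguous)")
  }
  tibble::as_tibble(out)
}

#' Identify internal-control contig pairs across the two libraries
#'
#' Internal-control contigs are the non-subtracted SSH background: highly
#' similar sequences present in both libraries at low counts. Candidate
#' pairs (sharing at least one 10-mer) are scored with a local alignment
#' (match +1, mismatch -2, gap open 5, gap extend 2) normalized by the
#' shorter sequence length; pairs are retained when they are reciprocal
#' best matches, similarity >= `min_similarity`, and both read counts are
#' <= `max_count`. Pairing is one-to-one.
#'
#' @param contigs_orange,contigs_green Contig tibbles.
#' @param min_similarity Minimum normalized similarity (default 0.9).
#' @param max_count Maximum read count on both sides (default 10).
#' @return An object of class `ssh_calibration` holding the control `pairs`
#'   (orange_id, green_id, similarity, count_orange, count_green) and, after
#'   [calibrate()], the scale factor.
#' @export
find_internal_controls <- function(contigs_orange, contigs_green,
                                   min_similarity = 0.9, max_count = 10) {
  if (nrow(contigs_orange) == 0 || nrow(contigs_green) == 0) {
    stop("both contig sets must be non-empty", call. = FALSE)
  }
  cand <- kmer_candidates(contigs_orange$sequence, contigs_green$sequence, 10L)
  if (nrow(cand) > 0) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(contigs_orange$sequence[cand$i]),
      Biostrings::DNAStringSet(contigs_green$sequence[cand$j]),
      type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
    cand$similarity <- sc / pmin(nchar(contigs_orange$sequence[cand$i]),
                                 nchar(contigs_green$sequence[cand$j]))
  } else {
    cand$similarity <- numeric()
  }
  cand <- cand[cand$similarity >= min_similarity, , drop = FALSE]
  pairs <- tibble(orange_id = character(), green_id = character(),
                  similarity = numeric(), count_orange = integer(),
                  count_green = integer())
  if (nrow(cand) > 0) {
    # reciprocal best match, deterministic tie-break by id order
    cand <- cand[order(-cand$similarity, cand$i, cand$j), ]
    best_for_o <- cand[!duplicated(cand$i), ]
    best_for_g <- cand[!duplicated(cand$j), ]
    recip <- dplyr::inner_join(
      best_for_o, best_for_g, by = c("i", "j", "similarity"))
    oc <- contigs_orange$read_count[recip$i]
    gc_ <- contigs_green$read_count[recip$j]
    keep <- oc <= max_count & gc_ <= max_count
    pairs <- tibble(
      orange_id = contigs_orange$contig_id[recip$i[keep]],
      green_id = contigs_green$contig_id[recip$j[keep]],
      similarity = recip$similarity[keep],
      count_orange = oc[keep], count_green = gc_[keep])
  }
  if (nrow(pairs) == 0) {
    stop("no internal-control pairs found; calibration impossible - ",
         "supply a scale factor explicitly", call. = FALSE)
  }
  structure(list(pairs = pairs, scale_factor = NULL, method = NULL),
            class = "ssh_calibration")
}

# candidate (i, j) index pairs sharing at least one k-mer
kmer_candidates <- function(a, b, k) {
  kmers <- function(x) {
    lapply(x, function(s) {
      if (nchar(s) < k) return(character())
      unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
    })
  }
  ka <- kmers(a); kb <- kmers(b)
  ta <- tibble(i = rep(seq_along(ka), lengths(ka)), kmer = unlist(ka))
  tb <- tibble(j = rep(seq_along(kb), lengths(kb)), kmer = unlist(kb))
  dplyr::inner_join(ta, tb, by = "kmer", relationship = "many-to-many") %>%
    dplyr::distinct(.data$i, .data$j)
}

#' Calibrate library sizes from internal-control pairs
#'
#' The scale factor is the ratio of summed orange control counts to summed
#' green control counts (ratio estimator; `method = "median"` uses the
#' median per-pair ratio instead). Green counts are multiplied by the scale
#' factor; orange counts are untouched. Calibrated counts stay real-valued.
#'
#' @param contigs Contig tibble (both variants or green only).
#' @param model An `ssh_calibration` from [find_internal_controls()].
#' @param method `"ratio"` (default) or `"median"`.
#' @return List: `contigs` (with `calibrated_count`) and `model` (with
#'   `scale_factor` filled in).
#' @export
calibrate <- function(contigs, model, method = c("ratio", "median")) {
  method <- match.arg(method)
  p <- model$pairs
  if (nrow(p) == 0) stop("calibration model has no control pairs", call. = FALSE)
  if (sum(p$count_green) == 0) {
    stop("green control counts sum to zero; cannot calibrate", call. = FALSE)
  }
  sf <- if (method == "ratio") sum(p$count_orange) / sum(p$count_green)
        else stats::median(p$count_orange / p$count_green)
  model$scale_factor <- sf
  model$method <- method
  contigs <- contigs %>%
    dplyr::mutate(calibrated_count = ifelse(.data$variant == "green",
                                            .data$read_count * sf,
                                            as.numeric(.data$read_count)))
  list(contigs = contigs, model = model)
}

#' Aggregate calibrated contig counts to gene level
#'
#' Gene-level counts are the sum of the assigned contigs' counts per
#' variant (multi-gene contigs are excluded upstream by the ambiguity rule).
#'
#' @param contigs Assigned, calibrated contig tibble.
#' @return Tibble: `gene_id`, `orange_raw`, `green_raw`, `orange`, `green`
#'   (calibrated).
#' @export
aggregate_gene_expression <- function(contigs) {
  if (!"calibrated_count" %in% names(contigs)) {
    contigs$calibrated_count <- as.numeric(contigs$read_count)
  }
  contigs %>%
    dplyr::filter(!is.na(.data$gene_id)) %>%
    dplyr::group_by(.data$gene_id, .data$variant) %>%
    dplyr::summarise(raw = sum(.data$read_count),
                     cal = sum(.data$calibrated_count), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "variant",
                       values_from = c("raw", "cal"), values_fill = 0) %>%
    add_missing_cols(c("raw_orange", "raw_green", "cal_orange", "cal_green")) %>%
    dplyr::transmute(.data$gene_id,
                     orange_raw = .data$raw_orange, green_raw = .data$raw_green,
                     orange = .data$cal_orange, green = .data$cal_green)
}

add_missing_cols <- function(x, cols) {
  for (cc in cols) if (!cc %in% names(x)) x[[cc]] <- 0
  x
}

#' Classify per-gene differential expression
#'
#' Classes, from calibrated counts: `strong` when one variant has at least
#' `strong_min` reads and the other none; `slight` when one side has at
#' least `slight_min` and the other none (and it is not strong); `moderate`
#' when both sides are positive, the larger is at least `slight_min`, and
#' the ratio is at least `fold`; otherwise `unchanged`. The suffix names
#' the higher variant (e.g. `strong_up_green`).
#'
#' @param expr Tibble from [aggregate_gene_expression()].
#' @param strong_min,slight_min,fold Thresholds (defaults 20, 5, 2).
#' @return `expr` with an added `class` column.
#' @export
classify_expression <- function(expr, strong_min = 20, slight_min = 5,
                                fold = 2) {
  if (any(expr$orange < 0 | expr$green < 0)) {
    stop("negative counts", call. = FALSE)
  }
  expr %>% dplyr::mutate(class = dplyr::case_when(
    .data$green >= strong_min & .data$orange == 0 ~ "strong_up_green",
    .data$orange >= strong_min & .data$green == 0 ~ "strong_down_green",
    .data$green >= slight_min & .data$orange == 0 ~ "slight_up_green",
    .data$orange >= slight_min & .data$green == 0 ~ "slight_down_green",
    .data$green > 0 & .data$orange > 0 & .data$green >= slight_min &
      .data$green >= fold * .data$orange ~ "moderate_up_green",
    .data$green > 0 & .data$orange > 0 & .data$orange >= slight_min &
      .data$orange >= fold * .data$green ~ "moderate_down_green",
    TRUE ~ "unchanged"))
}

#' @export
print.ssh_calibration <- function(x, ...) {
  cat("SSH internal-control calibration\n")
  cat("  control pairs:", nrow(x$pairs), "\n")
  if (!is.null(x$scale_factor)) {
    cat(sprintf("  scale factor (green x): %.4f  [method: %s]\n",
                x$scale_factor, x$method))
  } else {
    cat("  scale factor: not yet computed; run calibrate()\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the control pairs of a calibration model
#' @param x An `ssh_calibration`.
#' @param ... Unused.
#' @return Tibble of control pairs.
#' @method tidy ssh_calibration
#' @export
tidy.ssh_calibration <- function(x, ...) x$pairs

#' One-row summary of a calibration model
#' @param x An `ssh_calibration`.
#' @param ... Unused.
#' @return Tibble with `n_pairs`, `scale_factor`, `method`, summed counts.
#' @method glance ssh_calibration
#' @export
glance.ssh_calibration <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs),
         scale_factor = x$scale_factor %||% NA_real_,
         method = x$method %||% NA_character_,
         control_reads_orange = sum(x$pairs$count_orange),
         control_reads_green = sum(x$pairs$count_green))
}
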