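# Scaffold-level methylation-expression integration and track export.

#' Methylation-expression concordance over the most methylated scaffolds
#'
#' For the `top_k` scaffolds ranked by methylation density, compares the
#' methylation direction (which variant has more hits) with the net
#' expression direction (sign of the summed calibrated green-minus-orange
#' gene counts on the scaffold). A scaffold is concordant when methylation
#' is higher in green and expression lower in green, or the mirror case
#' (the inverse-correlation reading). Scaffolds with no expressed reads in
#' either variant are excluded from the denominator and reported
#' separately, as are scaffolds with tied direction on either axis.
#'
#' @param ranks Output of [rank_scaffolds()].
#' @param expression Classified gene table ([classify_expression()]).
#' @param genes Gene tibble mapping `gene_id` to `scaffold_id`.
#' @param top_k Number of top-ranked scaffolds to assess.
#' @return One-row tibble: `top_k`, `n_evaluated`, `n_silent`, `n_tied`,
#'   `n_concordant`, `fraction` (plus `fraction_of_top_k`, the variant of
#'   the statistic whose denominator keeps silent scaffolds).
#' @export
concordance <- function(ranks, expression, genes, top_k = 500) {
  if (top_k <= 0) stop("`top_k` must be positive", call. = FALSE)
  if (top_k > nrow(ranks)) {
    stop("`top_k` exceeds the number of scaffolds", call. = FALSE)
  }
  top <- ranks[order(ranks$rank), ][seq_len(top_k), ]
  expr_scf <- expression %>%
    dplyr::inner_join(genes[, c("gene_id", "scaffold_id")], by = "gene_id") %>%
    dplyr::group_by(.data$scaffold_id) %>%
    dplyr::summarise(net = sum(.data$green - .data$orange),
                     total = sum(.data$green + .data$orange),
                     .groups = "drop")
  d <- top %>% dplyr::left_join(expr_scf, by = "scaffold_id") %>%
    dplyr::mutate(
      net = dplyr::coalesce(.data$net, 0),
      total = dplyr::coalesce(.data$total, 0),
      meth_dir = sign(.data$hits_green - .data$hits_orange),
      expr_dir = sign(.data$net),
      silent = .data$total == 0,
      tied = !.data$silent & (.data$meth_dir == 0 | .data$expr_dir == 0),
      concordant = !.data$silent & !.data$tied &
        .data$meth_dir == -.data$expr_dir)
  n_silent <- sum(d$silent)
  n_tied <- sum(d$tied)
  n_eval <- top_k - n_silent - n_tied
  n_conc <- sum(d$concordant)
  tibble(top_k = top_k, n_evaluated = n_eval, n_silent = n_silent,
         n_tied = n_tied, n_concordant = n_conc,
         fraction = if (n_eval > 0) n_conc / n_eval else NA_real_,
         fraction_of_top_k = n_conc / top_k)
}

#' Export decorated-scaffold tracks
#'
#' Writes one methylation BED per variant (name = read id, score = copy
#' count), one expression GFF3 per variant (contig loci with a
#' `read_count` attribute), and a merged per-scaffold summary TSV. Record
#' order is deterministic (scaffold, start, id).
#'
#' @param placements Output of [place_reads()].
#' @param reads Read tibble with `variant`, `copy_count`.
#' @param contigs Assigned contig tibble (with locus columns).
#' @param ranks Output of [rank_scaffolds()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
export_tracks <- function(placements, reads, contigs, ranks, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  pl <- placements %>%
    dplyr::left_join(reads[, c("read_id", "variant", "copy_count")],
                     by = "read_id")
  for (v in c("orange", "green")) {
    path <- file.path(outdir, paste0("methylation_", v, ".bed"))
    pv <- pl %>% dplyr::filter(.data$variant == v) %>%
      dplyr::arrange(.data$scaffold_id, .data$start, .data$read_id) %>%
      dplyr::mutate(score = .data$copy_count)
    if (nrow(pv) == 0) {
      writeLines("# empty track", path)
    } else {
      write_bed(pv[, c("scaffold_id", "start", "end", "read_id", "score",
                       "strand")], path)
    }
    files <- c(files, path)
  }
  for (v in c("orange", "green")) {
    path <- file.path(outdir, paste0("expression_", v, ".gff3"))
    cv <- contigs %>%
      dplyr::filter(.data$variant == v, !is.na(.data$scaffold_id)) %>%
      dplyr::arrange(.data$scaffold_id, .data$locus_start, .data$contig_id)
    lines <- "##gff-version 3"
    if (nrow(cv) > 0) {
      lines <- c(lines, sprintf(
        "%s\tmethexpr\texpressed_sequence_match\t%d\t%d\t.\t.\t.\tID=%s;read_count=%d",
        cv$scaffold_id, cv$locus_start + 1L, cv$locus_end, cv$contig_id,
        cv$read_count))
    }
    writeLines(lines, path)
    files <- c(files, path)
  }
  path <- file.path(outdir, "scaffold_summary.tsv")
  readr::write_tsv(ranks %>% dplyr::arrange(.data$rank), path)
  files <- c(files, path)
  invisible(files)
}

#' Pipeline configuration: the analysis thresholds in one place
#'
#' Defaults are the conventional thresholds of this analysis: 4% mapper
#' mismatch cutoff, 2 kb / 3 kb promoter windows, 1 kb transposon borders
#' with a 49-51 kb distal control, strong / slight expression floors of 20
#' and 5 reads, two-fold change thresholds, alpha = 0.05, copy-count
#' thresholds 2 and 5, and top-500 / top-10,000 concordance windows. Every
#' threshold is overridable.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mismatch_fraction = 0.04,
    promoter_kb = 2, promoter2_kb = 3, border_kb = 1, distal_kb = c(49, 51),
    strong_min = 20, slight_min = 5, fold = 2, min_hits = 5,
    alpha = 0.05, copy_thresholds = c(2, 5), top_k = c(500, 10000),
    min_score = 60, min_similarity = 0.9, max_control_count = 10,
    stringency = "strong", seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    stop("unknown pipeline option(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full integrative pipeline
#'
#' Mapping, region quantification, SSH calibration, expression and
#' methylation classification, cross lists, GO enrichment, concordance,
#' and (optionally) track export, in one deterministic pass. Accepts
#' either an in-memory synthetic study (a [generate_genome()] bundle; the
#' reads and libraries are simulated from it) or a manifest of input
#' files.
#'
#' @param bundle A `genome_bundle`, or `NULL` when `manifest` is given.
#' @param config A [pipeline_config()].
#' @param manifest Named list of file paths with elements `scaffolds`,
#'   `genes`, `transposons`, `annotations`, `go_dag`, `reads_orange`,
#'   `reads_green`, `counts_orange`, `counts_green`, `contigs_orange`,
#'   `contigs_green`, `contig_counts_orange`, `contig_counts_green`.
#' @param outdir Optional directory for track export.
#' @return List of class `methexpr_result` with every stage's table and a
#'   `log` tibble of per-stage record counts.
#' @export
run_pipeline <- function(bundle = NULL, config = pipeline_config(),
                         manifest = NULL, outdir = NULL) {
  log <- list()
  note <- function(stage, n) log[[length(log) + 1]] <<- tibble(stage = stage, records = n)

  if (is.null(bundle)) {
    if (is.null(manifest)) stop("supply `bundle` or `manifest`", call. = FALSE)
    inputs <- load_manifest(manifest)
  } else {
    inputs <- simulate_study(bundle)
  }
  note("reads_orange", nrow(inputs$reads_orange))
  note("reads_green", nrow(inputs$reads_green))

  reads <- dplyr::bind_rows(inputs$reads_orange, inputs$reads_green)
  placements <- place_reads(reads, inputs$scaffolds,
                            mismatch_fraction = config$mismatch_fraction)
  note("placements", nrow(placements))

  scf_ids <- names(inputs$scaffolds)
  hits <- per_scaffold_hits(placements, reads, scf_ids)
  hw <- tidyr::pivot_wider(hits, names_from = "variant",
                           values_from = "hits", names_prefix = "hits_")
  hw <- add_missing_cols(hw, c("hits_orange", "hits_green"))
  r_scaffold <- pearson_correlation(hw$hits_orange, hw$hits_green)

  index <- build_region_index(inputs$genes, inputs$exons, inputs$transposons,
                              inputs$scaffold_lengths,
                              promoter_kb = config$promoter_kb,
                              promoter2_kb = config$promoter2_kb,
                              border_kb = config$border_kb,
                              distal_kb = config$distal_kb)
  counts <- count_by_region(placements, index, reads)
  note("region_counts", nrow(counts))
  meth <- classify_gene_methylation(counts, fold = config$fold,
                                    min_hits = config$min_hits)

  contigs <- dplyr::bind_rows(inputs$contigs_orange, inputs$contigs_green)
  contigs <- assign_contigs(contigs, inputs$scaffolds, inputs$genes,
                            min_score = config$min_score)
  note("contigs_assigned", sum(contigs$status == "assigned"))
  model <- find_internal_controls(inputs$contigs_orange, inputs$contigs_green,
                                  min_similarity = config$min_similarity,
                                  max_count = config$max_control_count)
  cal <- calibrate(contigs, model)
  contigs <- cal$contigs
  model <- cal$model
  note("control_pairs", nrow(model$pairs))

  expr <- classify_expression(aggregate_gene_expression(contigs),
                              strong_min = config$strong_min,
                              slight_min = config$slight_min,
                              fold = config$fold)
  note("genes_expressed", nrow(expr))

  lists <- build_cross_lists(expr, meth, stringency = config$stringency)
  anno <- propagate_annotations(inputs$annotations, inputs$dag)
  background <- unique(anno$gene_id)
  enrichments <- lists %>%
    dplyr::group_by(.data$list_id) %>%
    dplyr::group_map(function(d, key) {
      res <- suppressWarnings(suppressMessages(
        enrich(d$gene_id, background, anno, inputs$dag,
               alpha = config$alpha)))
      res$list_id <- key$list_id
      res
    }) %>%
    dplyr::bind_rows()
  note("enrichment_rows", nrow(enrichments))

  ranks <- rank_scaffolds(hits, inputs$scaffold_lengths)
  conc <- dplyr::bind_rows(lapply(
    pmin(config$top_k, nrow(ranks)) %>% unique(),
    function(k) concordance(ranks, expr, inputs$genes, k)))
  note("scaffolds_ranked", nrow(ranks))

  spectrum <- multiplicity_spectrum(placements, reads)
  occ <- occurrence_classes(inputs$reads_orange, inputs$reads_green,
                            t = config$copy_thresholds[1])

  result <- structure(list(
    placements = placements, reads = reads, spectrum = spectrum,
    occurrence = occ, scaffold_hits = hits, scaffold_correlation = r_scaffold,
    region_index = index, region_counts = counts, methylation = meth,
    contigs = contigs, calibration = model, expression = expr,
    cross_lists = lists, enrichment = enrichments, ranks = ranks,
    concordance = conc, config = config,
    log = dplyr::bind_rows(log)), class = "methexpr_result")

  if (!is.null(outdir)) {
    export_tracks(placements, reads, contigs, ranks, outdir)
  }
  result
}

# simulate the study inputs from a genome bundle
simulate_study <- function(bundle) {
  ssh <- simulate_ssh_libraries(bundle)
  list(
    scaffolds = bundle$scaffolds,
    scaffold_lengths = bundle$scaffold_lengths,
    genes = bundle$genes, exons = bundle$exons,
    transposons = bundle$transposons,
    annotations = bundle$annotations, dag = bundle$dag,
    reads_orange = simulate_methylome_reads(bundle, "orange"),
    reads_green = simulate_methylome_reads(bundle, "green"),
    contigs_orange = ssh$orange, contigs_green = ssh$green)
}

load_manifest <- function(manifest) {
  required <- c("scaffolds", "genes", "transposons", "annotations", "go_dag",
                "reads_orange", "reads_green", "contigs_orange",
                "contigs_green")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0) {
    stop("manifest missing input(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  scaffolds <- read_scaffolds_fasta(manifest$scaffolds)
  gx <- read_genes_gff3(manifest$genes)
  te <- read_bed(manifest$transposons) %>%
    dplyr::transmute(te_id = .data$name, .data$scaffold_id, .data$start,
                     .data$end)
  list(
    scaffolds = scaffolds,
    scaffold_lengths = setNames(nchar(scaffolds), names(scaffolds)),
    genes = gx$genes, exons = gx$exons, transposons = te,
    annotations = readr::read_tsv(manifest$annotations,
                                  show_col_types = FALSE),
    dag = read_obo(manifest$go_dag),
    reads_orange = read_reads_fasta(manifest$reads_orange,
                                    manifest$counts_orange, "orange"),
    reads_green = read_reads_fasta(manifest$reads_green,
                                   manifest$counts_green, "green"),
    contigs_orange = read_contigs(manifest$contigs_orange,
                                  manifest$contig_counts_orange, "orange"),
    contigs_green = read_contigs(manifest$contigs_green,
                                 manifest$contig_counts_green, "green"))
}

read_contigs <- function(fasta, tsv, variant) {
  x <- read_reads_fasta(fasta, tsv, variant)
  dplyr::transmute(x, contig_id = .data$read_id, .data$variant,
                   .data$sequence, read_count = .data$copy_count)
}

#' @export
print.methexpr_result <- function(x, ...) {
  cat("methexpr pipeline result\n")
  print(x$log)
  cat(sprintf("per-scaffold correlation r = %.3f\n", x$scaffold_correlation))
  if (nrow(x$concordance) > 0) {
    cat(sprintf("concordance (top %d): %.3f\n", x$concordance$top_k[1],
                x$concordance$fraction[1]))
  }
  invisible(x)
}
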