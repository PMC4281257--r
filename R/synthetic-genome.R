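#' Generate a synthetic two-variant genome bundle with planted truth
#'
#' Builds the full input set the pipeline consumes: genome scaffolds, gene
#' models (>= 2 exons each, stranded), transposon intervals, a GO DAG with
#' gene annotations, planted repeat units at exact copy numbers, per-variant
#' methylation hot spots, planted differentially expressed genes, and planted
#' enriched GO terms. Every planted feature is recorded in the returned
#' `truth` element so downstream stages can be scored against it.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `genome_bundle` with elements `config`,
#'   `scaffolds` (named character), `scaffold_lengths`, `genes`, `exons`,
#'   `transposons` (tibbles, 0-based half-open coordinates), `annotations`
#'   (gene_id, term_id), `dag` (a `go_dag`), and `truth` (a `planted_truth`).
#' @export
generate_genome <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(derive_seed(config$seed, "genome"))
  n_scf <- config$n_scaffolds
  L <- config$scaffold_length
  scf_ids <- sprintf("scf_%03d", seq_len(n_scf))

  scaffolds <- setNames(
    vapply(seq_len(n_scf), function(i) random_dna(L, config$gc_fraction), ""),
    scf_ids)

  gx <- lay_out_genes(scf_ids, L, config)
  genes <- gx$genes
  exons <- gx$exons
  transposons <- lay_out_transposons(scf_ids, L, genes, config)

  rep_tr <- plant_repeats(scaffolds, config)
  scaffolds <- rep_tr$scaffolds

  hotspots <- plant_hotspots(scf_ids, L, config)
  scaffold_direction <- infer_scaffold_direction(scf_ids, hotspots)

  de <- plant_de_genes(genes, scaffold_direction, config)
  meth_shift <- methylation_shift_table(genes, hotspots)

  go <- build_synthetic_go(genes, de, config)

  ctrl_pool <- setdiff(genes$gene_id, de$gene_id)
  n_ctl <- min(config$control_contig_count, length(ctrl_pool))
  control_genes <- tibble(
    pair_id = sprintf("ctl_%03d", seq_len(n_ctl)),
    gene_id = sample(ctrl_pool, n_ctl))

  truth <- structure(list(
    hotspots = hotspots,
    repeats = rep_tr$repeats,
    de_genes = de,
    methylation_shift = meth_shift,
    enriched_terms = go$enriched_terms,
    control_genes = control_genes,
    scaffold_direction = scaffold_direction,
    library_size_multiplier = config$library_size_multiplier
  ), class = "planted_truth")

  structure(list(
    config = config,
    scaffolds = scaffolds,
    scaffold_lengths = setNames(rep(L, n_scf), scf_ids),
    genes = genes, exons = exons, transposons = transposons,
    annotations = go$annotations, dag = go$dag,
    truth = truth
  ), class = "genome_bundle")
}

# Genes on a slot grid: each gene sits inside its own slot with a 3 kb
# leading margin (room for both promoter windows) and never overlaps a
# neighbour. 2-4 exons per gene; first and last segments are exons so that
# exon + intron intervals tile the gene body.
lay_out_genes <- function(scf_ids, L, config) {
  ng <- config$n_genes_per_scaffold
  if (ng == 0) {
    empty <- tibble(gene_id = character(), scaffold_id = character(),
                    start = integer(), end = integer(), strand = character())
    return(list(genes = empty,
                exons = dplyr::mutate(empty, exon_number = integer())))
  }
  slot <- floor(L / ng)
  genes <- list(); exons <- list(); k <- 0
  for (s in scf_ids) {
    for (g in seq_len(ng)) {
      k <- k + 1
      gene_id <- sprintf("gene_%04d", k)
      max_len <- min(6000, slot - 3500)
      len <- sample(seq(2000L, max_len), 1)
      lo <- (g - 1) * slot + 3000L
      hi <- g * slot - 500L - len
      start <- if (hi > lo) sample(seq(lo, hi), 1) else lo
      end <- start + len
      strand <- sample(c("+", "-"), 1)
      genes[[k]] <- tibble(gene_id = gene_id, scaffold_id = s,
                           start = start, end = end, strand = strand)
      n_ex <- sample(2:4, 1)
      # 2*n_ex - 1 alternating segments (exon, intron, ..., exon)
      nseg <- 2 * n_ex - 1
      w <- as.vector(stats::rmultinom(1, len - nseg * 60L, rep(1, nseg))) + 60L
      b <- start + cumsum(c(0L, w))
      idx <- seq(1, nseg, by = 2)
      exons[[k]] <- tibble(gene_id = gene_id, scaffold_id = s,
                           start = b[idx], end = b[idx + 1],
                           strand = strand, exon_number = seq_along(idx))
    }
  }
  list(genes = dplyr::bind_rows(genes), exons = dplyr::bind_rows(exons))
}

lay_out_transposons <- function(scf_ids, L, genes, config) {
  nt <- config$n_transposons_per_scaffold
  if (nt == 0) {
    return(tibble(te_id = character(), scaffold_id = character(),
                  start = integer(), end = integer()))
  }
  slot <- floor(L / nt)
  out <- list(); k <- 0
  for (s in scf_ids) {
    gs <- genes[genes$scaffold_id == s, ]
    for (t in seq_len(nt)) {
      k <- k + 1
      len <- sample(500:2500, 1)
      placed <- FALSE
      for (try in 1:20) {
        start <- (t - 1) * slot + sample(seq(0L, slot - len), 1)
        ov <- any(start < gs$end & (start + len) > gs$start)
        if (!ov) { placed <- TRUE; break }
      }
      out[[k]] <- tibble(te_id = sprintf("te_%04d", k), scaffold_id = s,
                         start = start, end = start + len)
    }
  }
  dplyr::bind_rows(out)
}

# One distinct random unit per requested copy number, spliced into the
# scaffolds at non-overlapping positions (coordinates recorded in truth).
plant_repeats <- function(scaffolds, config) {
  reps <- list(); occupied <- list()
  ulen <- config$repeat_unit_length
  scf_ids <- names(scaffolds)
  L <- nchar(scaffolds[[1]])
  for (i in seq_along(config$repeat_copy_numbers)) {
    cn <- config$repeat_copy_numbers[i]
    unit <- random_dna(ulen, 0.5)
    rows <- list()
    for (j in seq_len(cn)) {
      repeat {
        s <- sample(scf_ids, 1)
        at <- sample.int(L - ulen, 1) - 1L
        key_ok <- TRUE
        occ <- occupied[[s]]
        if (!is.null(occ) && any(at < occ[, 2] & (at + ulen) > occ[, 1])) key_ok <- FALSE
        if (key_ok) break
      }
      occupied[[s]] <- rbind(occupied[[s]], c(at, at + ulen))
      scaffolds[[s]] <- splice_in(scaffolds[[s]], at, unit)
      rows[[j]] <- tibble(unit_id = sprintf("rep_%02d", i), copy_number = cn,
                          sequence = unit, scaffold_id = s, start = at)
    }
    reps[[i]] <- dplyr::bind_rows(rows)
  }
  list(scaffolds = scaffolds, repeats = dplyr::bind_rows(reps))
}

# Hot spots: Poisson number per scaffold; a `shared_hotspot_fraction` of them
# is present in both variants, the rest are assigned to one variant
# independently per hot spot (Bernoulli 1/2).
plant_hotspots <- function(scf_ids, L, config) {
  out <- list(); k <- 0
  for (s in scf_ids) {
    n_h <- stats::rpois(1, config$hotspot_density * L / 1e5)
    if (n_h == 0) next
    for (h in seq_len(n_h)) {
      k <- k + 1
      w <- round(config$hotspot_width * stats::runif(1, 0.75, 1.25))
      start <- sample.int(max(1L, L - w), 1) - 1L
      variant <- if (stats::runif(1) < config$shared_hotspot_fraction) "both"
                 else sample(c("orange", "green"), 1)
      out[[k]] <- tibble(scaffold_id = s, start = start, end = start + w,
                         variant = variant, weight = config$fragment_capture_bias)
    }
  }
  if (k == 0) {
    return(tibble(scaffold_id = character(), start = integer(), end = integer(),
                  variant = character(), weight = numeric()))
  }
  dplyr::bind_rows(out)
}

# Emergent per-scaffold methylation direction: the variant holding the larger
# total variant-specific hot-spot mass (weight x width). Ties -> "none".
infer_scaffold_direction <- function(scf_ids, hotspots) {
  spec <- hotspots[hotspots$variant %in% c("orange", "green"), ]
  mass <- spec %>%
    dplyr::mutate(mass = .data$weight * (.data$end - .data$start)) %>%
    dplyr::group_by(.data$scaffold_id, .data$variant) %>%
    dplyr::summarise(mass = sum(.data$mass), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "variant", values_from = "mass",
                       values_fill = 0)
  for (v in c("orange", "green")) if (is.null(mass[[v]])) mass[[v]] <- 0
  tibble(scaffold_id = scf_ids) %>%
    dplyr::left_join(mass, by = "scaffold_id") %>%
    dplyr::mutate(
      orange = dplyr::coalesce(.data$orange, 0),
      green = dplyr::coalesce(.data$green, 0),
      direction = dplyr::case_when(
        .data$green > .data$orange ~ "green",
        .data$orange > .data$green ~ "orange",
        TRUE ~ "none")) %>%
    dplyr::select("scaffold_id", "direction")
}

# DE genes: direction opposes the scaffold's methylation direction with
# probability `inverse_coupling` ("green" methylation direction -> expression
# down in green), otherwise random.
plant_de_genes <- function(genes, scaffold_direction, config) {
  n_de <- round(config$de_gene_fraction * nrow(genes))
  if (n_de == 0) {
    return(tibble(gene_id = character(), direction = character(),
                  fold = numeric()))
  }
  picked <- genes[sort(sample.int(nrow(genes), n_de)), ] %>%
    dplyr::left_join(scaffold_direction, by = "scaffold_id")
  dir <- vapply(picked$direction, function(d) {
    anti <- switch(d, green = "down_green", orange = "up_green",
                   sample(c("up_green", "down_green"), 1))
    if (d != "none" && stats::runif(1) < config$inverse_coupling) anti
    else sample(c("up_green", "down_green"), 1)
  }, "")
  tibble(gene_id = picked$gene_id, direction = unname(dir),
         fold = config$de_fold_change)
}

# Genes whose body or 0-2 kb promoter overlaps a variant-specific hot spot
# are expected to shift methylation toward that variant.
methylation_shift_table <- function(genes, hotspots) {
  spec <- hotspots[hotspots$variant %in% c("orange", "green"), ]
  if (nrow(spec) == 0 || nrow(genes) == 0) {
    return(tibble(gene_id = character(), region = character(),
                  direction = character()))
  }
  regions <- dplyr::bind_rows(
    dplyr::mutate(genes, region = "gene_body"),
    genes %>% dplyr::mutate(
      region = "promoter_0_2kb",
      end2 = ifelse(.data$strand == "+", .data$start, .data$end + 2000L),
      start2 = ifelse(.data$strand == "+", pmax(0L, .data$start - 2000L), .data$end),
      start = .data$start2, end = .data$end2) %>%
      dplyr::select(-"start2", -"end2"))
  dplyr::inner_join(regions, spec, by = "scaffold_id",
                    relationship = "many-to-many") %>%
    dplyr::filter(.data$start.x < .data$end.y, .data$end.x > .data$start.y) %>%
    dplyr::distinct(.data$gene_id, .data$region, direction = .data$variant)
}

# Synthetic GO DAG over the three namespaces plus planted enriched terms.
# Every non-root term gets 1-2 parents among earlier terms of its namespace,
# so the graph is acyclic by construction.
build_synthetic_go <- function(genes, de, config) {
  ns_names <- c("molecular_function", "biological_process", "cellular_component")
  n_terms <- config$go_term_count
  ns_alloc <- ns_names[1 + (seq_len(n_terms) - 1) %% 3]
  roots <- tibble(
    term_id = sprintf("GO:%07d", 1:3), name = paste0(ns_names, "_root"),
    namespace = ns_names)
  terms <- tibble(
    term_id = sprintf("GO:%07d", 3 + seq_len(n_terms)),
    name = sprintf("synthetic term %03d", seq_len(n_terms)),
    namespace = ns_alloc)
  parents <- list()
  for (i in seq_len(n_terms)) {
    ns <- ns_alloc[i]
    pool <- c(roots$term_id[roots$namespace == ns],
              terms$term_id[seq_len(i - 1)][ns_alloc[seq_len(i - 1)] == ns])
    np <- min(length(pool), sample(1:2, 1))
    parents[[i]] <- tibble(term_id = terms$term_id[i],
                           parent_id = sample(pool, np))
  }
  dag <- go_dag(dplyr::bind_rows(roots, terms), dplyr::bind_rows(parents))

  # background annotations: 1-3 uniform terms per gene
  anno <- lapply(genes$gene_id, function(g) {
    tibble(gene_id = g,
           term_id = sample(terms$term_id, sample(1:3, 1)))
  })
  anno <- dplyr::bind_rows(anno)

  # planted enrichment: dedicate terms (never reused as background favourites)
  # to alternating DE lists; annotate 60% of the target list and 3% of the rest
  n_pl <- config$planted_enriched_terms
  enriched <- tibble(term_id = character(), target_list = character())
  if (n_pl > 0 && nrow(de) > 0) {
    pl_terms <- sample(terms$term_id[terms$namespace == "molecular_function"], n_pl)
    targets <- rep(c("up_green", "down_green"), length.out = n_pl)
    extra <- list()
    for (i in seq_len(n_pl)) {
      tgt <- de$gene_id[de$direction == targets[i]]
      if (length(tgt) == 0) tgt <- de$gene_id
      hit <- sample(tgt, max(1, round(0.6 * length(tgt))))
      bg <- setdiff(genes$gene_id, tgt)
      bg_hit <- sample(bg, round(0.03 * length(bg)))
      extra[[i]] <- tibble(gene_id = c(hit, bg_hit), term_id = pl_terms[i])
    }
    anno <- dplyr::bind_rows(anno, dplyr::bind_rows(extra)) %>%
      dplyr::distinct()
    enriched <- tibble(term_id = pl_terms, target_list = targets)
  }
  list(dag = dag, annotations = anno, enriched_terms = enriched)
}
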