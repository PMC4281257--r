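#' Simulate the two SSH cDNA libraries with planted truth
#'
#' Emits, per variant, a contig table with read counts:
#'
#' * internal-control contigs — identical sequence pairs (one per planted
#'   control gene) carried by both libraries at similar low counts. Each pair
#'   draws a shared latent level uniformly on `config$control_count_range`
#'   and adds independent unit jitter per side, emulating the non-subtracted
#'   linear background of the SSH protocol.
#' * DE contigs — one subsequence per planted DE gene, present with a high
#'   count (`strong_read_base` + Poisson excess scaled by `de_fold_change`)
#'   in the up variant only and absent from the other.
#'
#' The green library's counts are then scaled by the planted library-size
#' multiplier (stochastic rounding, floor of 1 read), which the calibration
#' stage is expected to undo.
#'
#' @param bundle A [generate_genome()] bundle.
#' @param seed Integer seed (default derived from the bundle's config).
#' @param multiplier Library-size multiplier applied to green (defaults to
#'   the planted `truth$library_size_multiplier`).
#' @return List with tibbles `orange` and `green` (`contig_id`, `variant`,
#'   `sequence`, `read_count`) and `controls` (`pair_id`, `orange_id`,
#'   `green_id`, `gene_id`) naming the planted control pairs.
#' @export
simulate_ssh_libraries <- function(bundle, seed = NULL, multiplier = NULL) {
  config <- bundle$config
  truth <- bundle$truth
  if (config$de_gene_fraction == 0 && config$planted_enriched_terms > 0) {
    stop("planted_enriched_terms > 0 requires planted DE genes", call. = FALSE)
  }
  seed <- seed %||% derive_seed(config$seed, "ssh")
  multiplier <- multiplier %||% truth$library_size_multiplier
  set.seed(seed)

  gene_seq <- function(gene_id, lo, hi) {
    g <- bundle$genes[bundle$genes$gene_id == gene_id, ]
    len <- min(sample(lo:hi, 1), g$end - g$start)
    at <- g$start + sample.int(g$end - g$start - len + 1L, 1) - 1L
    substring(bundle$scaffolds[[g$scaffold_id]], at + 1, at + len)
  }

  orange <- list(); green <- list(); controls <- list()
  cc <- truth$control_genes
  rng <- config$control_count_range
  for (i in seq_len(nrow(cc))) {
    sq <- gene_seq(cc$gene_id[i], 200L, 400L)
    u <- sample(rng[1]:rng[2], 1)
    oc <- max(1L, u + sample(-1:1, 1))
    gc_ <- max(1L, u + sample(-1:1, 1))
    oid <- paste0("o_", cc$pair_id[i]); gid <- paste0("g_", cc$pair_id[i])
    orange[[length(orange) + 1]] <- tibble(
      contig_id = oid, variant = "orange", sequence = sq, read_count = oc)
    green[[length(green) + 1]] <- tibble(
      contig_id = gid, variant = "green", sequence = sq, read_count = gc_)
    controls[[i]] <- tibble(pair_id = cc$pair_id[i], orange_id = oid,
                            green_id = gid, gene_id = cc$gene_id[i])
  }

  de <- truth$de_genes
  for (i in seq_len(nrow(de))) {
    sq <- gene_seq(de$gene_id[i], 250L, 500L)
    cnt <- config$strong_read_base +
      stats::rpois(1, config$strong_read_base * (de$fold[i] - 1))
    row <- tibble(contig_id = sprintf("de_%s", de$gene_id[i]),
                  sequence = sq, read_count = cnt)
    if (de$direction[i] == "up_green") {
      green[[length(green) + 1]] <- dplyr::mutate(row, variant = "green")
    } else {
      orange[[length(orange) + 1]] <- dplyr::mutate(row, variant = "orange")
    }
  }

  green_tbl <- dplyr::bind_rows(green)
  if (multiplier != 1 && nrow(green_tbl) > 0) {
    green_tbl$read_count <- pmax(1L, stochastic_round(
      green_tbl$read_count * multiplier))
  }
  list(orange = dplyr::bind_rows(orange),
       green = dplyr::select(green_tbl, "contig_id", "variant",
                             "sequence", "read_count"),
       controls = dplyr::bind_rows(controls))
}

stochastic_round <- function(x) {
  f <- floor(x)
  as.integer(f + stats::rbinom(length(x), 1, x - f))
}
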