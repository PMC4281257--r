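#' Configuration for the synthetic two-variant study
#'
#' Bundles every tunable of the synthetic-data generator. The defaults define
#' the reference simulated study: a 5 Mb genome (50 scaffolds of 100 kb) of an
#' AT-rich insect-like composition, two clonal variants (*orange* and *green*)
#' sharing half of their methylation hot spots, 2e5 methyl-enriched reads per
#' variant, and two SSH libraries with a low-count internal-control background
#' plus planted strongly differential genes whose direction is inversely
#' coupled to the scaffold's methylation direction.
#'
#' @param seed Integer seed; all stages derive child seeds from it, so an
#'   identical config is byte-reproducible.
#' @param n_scaffolds Number of genome scaffolds.
#' @param scaffold_length Length of each scaffold (bp).
#' @param gc_fraction GC content of the random background sequence.
#' @param n_genes_per_scaffold Gene models per scaffold (non-overlapping,
#'   each with >= 2 exons and a strand).
#' @param n_transposons_per_scaffold Transposon intervals per scaffold.
#' @param repeat_unit_length Length (bp) of each planted repeat unit.
#' @param repeat_copy_numbers Integer vector; one distinct repeat unit is
#'   planted per entry, at exactly that many genome-wide copies.
#' @param hotspot_density Methylation hot spots per 100 kb of scaffold.
#' @param hotspot_width Hot-spot interval width (bp).
#' @param shared_hotspot_fraction Proportion of hot spots present in both
#'   variants; the rest are assigned to one variant independently per hot spot.
#' @param reads_per_variant Total methyl-read copies sampled per variant.
#' @param fragment_capture_bias Multiplier on the sampling weight of MseI
#'   fragments overlapping a hot spot of the sampled variant.
#' @param min_fragment_length Fragments shorter than this are not sequenced.
#' @param de_gene_fraction Proportion of genes planted as strongly
#'   differentially expressed.
#' @param de_fold_change Expected fold excess of planted DE contig counts over
#'   the strong-expression floor (`strong_read_base`); must be >= 1.
#' @param strong_read_base Minimum read count planted for a strong DE contig.
#' @param control_contig_count Number of internal-control contig pairs.
#' @param control_count_range Length-2 integer range of the shared latent
#'   count level of control contigs.
#' @param go_term_count Number of GO terms in the synthetic DAG (across the
#'   three namespaces, roots excluded).
#' @param planted_enriched_terms Number of GO terms planted as enriched in
#'   the DE gene lists.
#' @param inverse_coupling Probability that a planted DE gene's direction
#'   opposes its scaffold's methylation direction.
#' @param library_size_multiplier Global multiplier applied to the green SSH
#'   library's counts (recorded in the planted truth; the calibration stage
#'   should recover its reciprocal).
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_scaffolds = 50L,
                             scaffold_length = 100000L,
                             gc_fraction = 0.35,
                             n_genes_per_scaffold = 8L,
                             n_transposons_per_scaffold = 4L,
                             repeat_unit_length = 40L,
                             repeat_copy_numbers = c(1L, 2L, 5L, 50L),
                             hotspot_density = 8,
                             hotspot_width = 2000L,
                             shared_hotspot_fraction = 0.5,
                             reads_per_variant = 200000L,
                             fragment_capture_bias = 10,
                             min_fragment_length = 30L,
                             de_gene_fraction = 0.3,
                             de_fold_change = 4,
                             strong_read_base = 20L,
                             control_contig_count = 60L,
                             control_count_range = c(2L, 8L),
                             go_term_count = 150L,
                             planted_enriched_terms = 3L,
                             inverse_coupling = 0.9,
                             library_size_multiplier = 1) {
  cfg <- list(
    seed = as.integer(seed),
    n_scaffolds = n_scaffolds, scaffold_length = scaffold_length,
    gc_fraction = gc_fraction,
    n_genes_per_scaffold = n_genes_per_scaffold,
    n_transposons_per_scaffold = n_transposons_per_scaffold,
    repeat_unit_length = repeat_unit_length,
    repeat_copy_numbers = as.integer(repeat_copy_numbers),
    hotspot_density = hotspot_density, hotspot_width = hotspot_width,
    shared_hotspot_fraction = shared_hotspot_fraction,
    reads_per_variant = reads_per_variant,
    fragment_capture_bias = fragment_capture_bias,
    min_fragment_length = min_fragment_length,
    de_gene_fraction = de_gene_fraction, de_fold_change = de_fold_change,
    strong_read_base = strong_read_base,
    control_contig_count = control_contig_count,
    control_count_range = as.integer(control_count_range),
    go_term_count = go_term_count,
    planted_enriched_terms = planted_enriched_terms,
    inverse_coupling = inverse_coupling,
    library_size_multiplier = library_size_multiplier
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  for (f in c("gc_fraction", "shared_hotspot_fraction", "de_gene_fraction",
              "inverse_coupling")) {
    stopifnot_prop(cfg[[f]], f)
  }
  for (f in c("n_scaffolds", "scaffold_length", "n_genes_per_scaffold",
              "n_transposons_per_scaffold", "repeat_unit_length",
              "reads_per_variant", "control_contig_count", "go_term_count",
              "planted_enriched_terms", "min_fragment_length",
              "strong_read_base")) {
    stopifnot_count(cfg[[f]], f)
  }
  if (cfg$de_fold_change < 1) stop("`de_fold_change` must be >= 1", call. = FALSE)
  if (cfg$fragment_capture_bias <= 0) stop("`fragment_capture_bias` must be > 0", call. = FALSE)
  if (cfg$library_size_multiplier <= 0) stop("`library_size_multiplier` must be > 0", call. = FALSE)
  if (any(cfg$repeat_copy_numbers < 1)) stop("`repeat_copy_numbers` must be >= 1", call. = FALSE)
  if (cfg$de_gene_fraction == 0 && cfg$planted_enriched_terms > 0) {
    stop("`planted_enriched_terms` > 0 requires `de_gene_fraction` > 0: ",
         "enriched terms are planted on DE gene lists", call. = FALSE)
  }
  # packing feasibility: each gene needs its slot to hold a 3 kb promoter
  # margin plus a minimal 2 kb gene and 500 bp trailing gap
  if (cfg$n_genes_per_scaffold > 0) {
    slot <- cfg$scaffold_length / cfg$n_genes_per_scaffold
    if (slot < 5500) {
      stop("infeasible packing: n_genes_per_scaffold * 5.5 kb exceeds ",
           "scaffold_length (each gene slot needs >= 5,500 bp)", call. = FALSE)
    }
  }
  if (cfg$n_transposons_per_scaffold > 0 &&
      cfg$scaffold_length / cfg$n_transposons_per_scaffold < 3000) {
    stop("infeasible packing: n_transposons_per_scaffold * 3 kb exceeds ",
         "scaffold_length", call. = FALSE)
  }
  invisible(cfg)
}
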