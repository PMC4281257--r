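# Readers and writers for the interchange formats. Internal coordinates are
# 0-based half-open everywhere; GFF3 (1-based inclusive) and BED (0-based
# half-open) conversions happen only at these boundaries, via rtracklayer.

#' Write genome scaffolds to FASTA
#' @param scaffolds Named character vector.
#' @param path Output FASTA path.
#' @export
write_scaffolds_fasta <- function(scaffolds, path) {
  x <- Biostrings::DNAStringSet(scaffolds)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read genome scaffolds from FASTA
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_scaffolds_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write reads or contigs as FASTA plus a copy-count TSV
#'
#' Identical sequencing reads are collapsed to one FASTA record and a count
#' column in a side table, keeping fixtures small. [read_reads_fasta()]
#' accepts both representations: if the TSV is absent every record counts 1.
#'
#' @param reads Tibble with `read_id`, `sequence` and a count column.
#' @param fasta,tsv Output paths.
#' @param count_col Name of the count column (`"copy_count"` for methyl
#'   reads, `"read_count"` for SSH contigs).
#' @export
write_reads_fasta <- function(reads, fasta, tsv = NULL,
                              count_col = "copy_count") {
  id_col <- if ("read_id" %in% names(reads)) "read_id" else "contig_id"
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads[[id_col]]))
  Biostrings::writeXStringSet(x, fasta)
  if (!is.null(tsv)) {
    readr::write_tsv(reads[, c(id_col, count_col)], tsv)
  }
  invisible(fasta)
}

#' Read reads/contigs from FASTA with an optional copy-count TSV
#' @param fasta FASTA path.
#' @param tsv Optional TSV path with the id column and a count column.
#' @param variant Optional variant label attached to every read.
#' @return Tibble with `read_id`, `sequence`, `copy_count` (and `variant`).
#' @export
read_reads_fasta <- function(fasta, tsv = NULL, variant = NULL) {
  x <- Biostrings::readDNAStringSet(fasta)
  out <- tibble(read_id = sub("\\s.*", "", names(x)),
                sequence = as.character(x))
  if (!is.null(tsv)) {
    cc <- readr::read_tsv(tsv, show_col_types = FALSE)
    names(cc)[1] <- "read_id"
    names(cc)[2] <- "copy_count"
    out <- dplyr::left_join(out, cc, by = "read_id")
    out$copy_count[is.na(out$copy_count)] <- 1L
  } else {
    out$copy_count <- 1L
  }
  if (!is.null(variant)) out$variant <- variant
  out
}

#' Write gene models to GFF3 (1-based inclusive)
#' @param genes,exons Gene/exon tibbles (0-based half-open).
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genes, exons, path) {
  if (nrow(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  g <- GenomicRanges::GRanges(
    genes$scaffold_id, IRanges::IRanges(genes$start + 1, genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id)
  e <- GenomicRanges::GRanges(
    exons$scaffold_id, IRanges::IRanges(exons$start + 1, exons$end),
    strand = exons$strand, type = "exon",
    ID = sprintf("%s.exon%d", exons$gene_id, exons$exon_number),
    Parent = exons$gene_id)
  rtracklayer::export(c(g, e), path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 path.
#' @return List of tibbles `genes` and `exons` (0-based half-open).
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    genes <- tibble(gene_id = character(), scaffold_id = character(),
                    start = integer(), end = integer(), strand = character())
    return(list(genes = genes,
                exons = dplyr::mutate(genes, exon_number = integer())))
  }
  d <- tibble(
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type), ID = as.character(gr$ID),
    Parent = vapply(as.list(gr$Parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, ""))
  genes <- d %>% dplyr::filter(.data$type == "gene") %>%
    dplyr::transmute(gene_id = .data$ID, .data$scaffold_id, .data$start,
                     .data$end, .data$strand)
  exons <- d %>% dplyr::filter(.data$type == "exon") %>%
    dplyr::group_by(.data$Parent) %>%
    dplyr::arrange(.data$start, .by_group = TRUE) %>%
    dplyr::mutate(exon_number = dplyr::row_number()) %>%
    dplyr::ungroup() %>%
    dplyr::transmute(gene_id = .data$Parent, .data$scaffold_id, .data$start,
                     .data$end, .data$strand, .data$exon_number)
  list(genes = genes, exons = exons)
}

#' Write intervals to BED (0-based half-open)
#' @param x Tibble with `scaffold_id`, `start`, `end` and optionally a name
#'   column (first of `te_id`/`read_id`/`name`), `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  name_col <- intersect(c("te_id", "read_id", "name"), names(x))[1]
  n <- nrow(x)
  bed <- tibble(
    chrom = x$scaffold_id, start = x$start, end = x$end,
    name = if (!is.na(name_col)) x[[name_col]] else sprintf("f%05d", seq_len(n)),
    score = if ("score" %in% names(x)) x$score else 0L,
    strand = if ("strand" %in% names(x)) x$strand else ".")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file (0-based half-open, 3-6 columns)
#' @param path BED path.
#' @return Tibble with `scaffold_id`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("scaffold_id", "start", "end", "name", "score", "strand")
  d <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       comment = "#")
  if (nrow(d) == 0) {
    return(tibble(scaffold_id = character(), start = integer(),
                  end = integer(), name = character(), score = numeric(),
                  strand = character()))
  }
  names(d) <- cols[seq_len(ncol(d))]
  if (is.null(d$name)) d$name <- NA_character_
  if (is.null(d$score)) d$score <- 0
  if (is.null(d$strand)) d$strand <- "."
  tibble::as_tibble(d)
}

#' Serialize a genome bundle to a directory of plain-text files
#'
#' Writes `scaffolds.fa`, `genes.gff3`, `transposons.bed`,
#' `annotations.tsv`, `go.obo`, `config.yaml`, and the planted truth tables
#' under `truth/`.
#' @param bundle A [generate_genome()] bundle.
#' @param dir Output directory (created if missing).
#' @export
write_genome_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_scaffolds_fasta(bundle$scaffolds, file.path(dir, "scaffolds.fa"))
  write_genes_gff3(bundle$genes, bundle$exons, file.path(dir, "genes.gff3"))
  write_bed(bundle$transposons, file.path(dir, "transposons.bed"))
  readr::write_tsv(bundle$annotations, file.path(dir, "annotations.tsv"))
  write_obo(bundle$dag, file.path(dir, "go.obo"))
  yaml::write_yaml(unclass(bundle$config), file.path(dir, "config.yaml"))
  tr <- bundle$truth
  for (nm in setdiff(names(tr), "library_size_multiplier")) {
    readr::write_tsv(tr[[nm]], file.path(dir, "truth", paste0(nm, ".tsv")))
  }
  yaml::write_yaml(list(library_size_multiplier = tr$library_size_multiplier),
                   file.path(dir, "truth", "scalars.yaml"))
  invisible(dir)
}

#' Read back a serialized genome bundle
#' @param dir Directory written by [write_genome_bundle()].
#' @return A `genome_bundle` list.
#' @export
read_genome_bundle <- function(dir) {
  scaffolds <- read_scaffolds_fasta(file.path(dir, "scaffolds.fa"))
  gx <- read_genes_gff3(file.path(dir, "genes.gff3"))
  te <- read_bed(file.path(dir, "transposons.bed")) %>%
    dplyr::transmute(te_id = .data$name, .data$scaffold_id, .data$start,
                     .data$end)
  anno <- readr::read_tsv(file.path(dir, "annotations.tsv"),
                          show_col_types = FALSE)
  dag <- read_obo(file.path(dir, "go.obo"))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$repeat_copy_numbers <- as.integer(cfg$repeat_copy_numbers)
  cfg$control_count_range <- as.integer(cfg$control_count_range)
  cfg <- structure(cfg, class = "synthetic_config")
  tdir <- file.path(dir, "truth")
  truth <- list()
  for (f in list.files(tdir, pattern = "\\.tsv$")) {
    truth[[sub("\\.tsv$", "", f)]] <-
      readr::read_tsv(file.path(tdir, f), show_col_types = FALSE)
  }
  sc <- yaml::read_yaml(file.path(tdir, "scalars.yaml"))
  truth$library_size_multiplier <- sc$library_size_multiplier
  structure(list(
    config = cfg, scaffolds = scaffolds,
    scaffold_lengths = setNames(nchar(scaffolds), names(scaffolds)),
    genes = gx$genes, exons = gx$exons, transposons = te,
    annotations = anno, dag = dag,
    truth = structure(truth, class = "planted_truth")
  ), class = "genome_bundle")
}
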