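# ggplot2 convenience views of the main result types.

#' Plot the multiplicity spectrum
#' @param spectrum Output of [multiplicity_spectrum()].
#' @return A ggplot.
#' @export
plot_multiplicity_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$n_locations, y = .data$n_reads,
                               colour = .data$variant)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic locations per distinct read",
                  y = "distinct reads", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of per-scaffold hits between the two variants
#' @param hits Output of [per_scaffold_hits()].
#' @return A ggplot annotated with the Pearson coefficient.
#' @export
plot_scaffold_hits <- function(hits) {
  w <- tidyr::pivot_wider(hits, names_from = "variant", values_from = "hits",
                          names_prefix = "hits_", values_fill = 0)
  w <- add_missing_cols(w, c("hits_orange", "hits_green"))
  r <- pearson_correlation(w$hits_orange, w$hits_green)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$hits_orange,
                                  y = .data$hits_green)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "hits per scaffold (orange)",
                  y = "hits per scaffold (green)",
                  subtitle = sprintf("r = %.3f", r)) +
    ggplot2::theme_minimal()
}

#' Bar chart of hits per genomic region class
#' @param counts Output of [count_by_region()].
#' @return A ggplot.
#' @export
plot_region_counts <- function(counts) {
  totals <- region_class_totals(counts)
  ggplot2::ggplot(totals,
                  ggplot2::aes(x = .data$class, y = .data$hits,
                               fill = .data$variant)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "copy-weighted hits", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Top enriched terms of an enrichment result
#' @param object A `go_enrichment`.
#' @param n_terms Number of top terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot of -log10 p per term.
#' @method autoplot go_enrichment
#' @export
autoplot.go_enrichment <- function(object, n_terms = 15, ...) {
  d <- utils::head(tidy(object), n_terms)
  d$name <- factor(d$name, levels = rev(d$name))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_value), y = .data$name,
                                  fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha")),
                        linetype = 2) +
    ggplot2::labs(y = NULL, x = expression(-log[10] ~ p), fill = "enriched") +
    ggplot2::theme_minimal()
}
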