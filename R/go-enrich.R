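# Hypergeometric GO-term enrichment over the ontology DAG.

#' Propagate gene annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to all its `is_a`
#' ancestors; this closes each gene's term set under ancestry. Idempotent.
#' Annotations to unknown terms are dropped with a warning.
#'
#' @param annotations Tibble with `gene_id`, `term_id`.
#' @param dag A [go_dag()].
#' @return Tibble `gene_id`, `term_id`, closed under ancestry.
#' @export
propagate_annotations <- function(annotations, dag) {
  if (nrow(annotations) == 0) return(annotations)
  unknown <- setdiff(unique(annotations$term_id), dag$terms$term_id)
  if (length(unknown) > 0) {
    warning(length(unknown), " annotation term(s) absent from the ontology ",
            "dropped: ", paste(utils::head(unknown, 5), collapse = ", "),
            call. = FALSE)
    annotations <- annotations[!annotations$term_id %in% unknown, ]
  }
  anc <- go_ancestors(dag, unique(annotations$term_id))
  annotations %>%
    dplyr::mutate(term_id = unname(anc[.data$term_id])) %>%
    tidyr::unnest_longer("term_id") %>%
    dplyr::distinct(.data$gene_id, .data$term_id)
}

#' Upper-tail hypergeometric p-value for term enrichment
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, m, n)`: the probability that a
#' uniform size-`n` gene list drawn from `N` background genes, `m` of which
#' carry the term, contains `k` or more carriers. Computed as a log-space
#' sum of binomial coefficients, stable up to `N` of about 1e6.
#'
#' @param N Background size (genes with any annotation).
#' @param m Background genes carrying the term.
#' @param n Query-list size.
#' @param k Query genes carrying the term.
#' @return The p-value in (0, 1].
#' @export
hypergeometric_pvalue <- function(N, m, n, k) {
  if (k < 0) stop("violated precondition: k >= 0", call. = FALSE)
  if (k > min(m, n)) stop("violated precondition: k <= min(m, n)", call. = FALSE)
  if (m > N) stop("violated precondition: m <= N", call. = FALSE)
  if (n > N) stop("violated precondition: n <= N", call. = FALSE)
  if (k == 0) return(1)
  i <- k:min(m, n)
  # P(X = i) = C(m, i) C(N - m, n - i) / C(N, n)
  lp <- lchoose(m, i) + lchoose(N - m, n - i) - lchoose(N, n)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Build expression x methylation cross lists
#'
#' Emits the gene-list family used for enrichment: each expression
#' direction (up / down in green) crossed with no methylation filter, a
#' two-fold methylation increase, or a two-fold decrease, the methylation
#' filters evaluated in the gene body and in the 0-2 kb promoter.
#' Expression stringency is cumulative: `"strong"` keeps only strong
#' classes, `"slight"` adds slight, `"moderate"` adds moderate.
#'
#' @param expression Classified table from [classify_expression()].
#' @param methylation Records from [classify_gene_methylation()].
#' @param stringency `"strong"`, `"slight"` or `"moderate"`.
#' @return Tibble: `list_id`, `expression`, `methylation`, `region`,
#'   `gene_id`.
#' @export
build_cross_lists <- function(expression, methylation,
                              stringency = c("strong", "slight", "moderate")) {
  stringency <- match.arg(stringency)
  levels <- switch(stringency,
                   strong = "strong",
                   slight = c("strong", "slight"),
                   moderate = c("strong", "slight", "moderate"))
  out <- list()
  for (dir in c("up", "down")) {
    expr_classes <- paste0(levels, "_", dir, "_green")
    members <- expression$gene_id[expression$class %in% expr_classes]
    out[[length(out) + 1]] <- tibble(
      list_id = paste0("expr_", dir), expression = dir,
      methylation = "none", region = NA_character_, gene_id = members)
    for (mdir in c("up", "down")) {
      mclass <- paste0(mdir, "2x_green")
      for (reg in c("gene_body", "promoter_0_2kb")) {
        mg <- methylation$gene_id[methylation$region == reg &
                                    methylation$class == mclass]
        out[[length(out) + 1]] <- tibble(
          list_id = paste("expr", dir, "meth", mdir, reg, sep = "_"),
          expression = dir, methylation = mdir, region = reg,
          gene_id = intersect(members, mg))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Hypergeometric GO-term enrichment of a gene list
#'
#' Tests every term carried by at least one query gene against the
#' annotated background. `N` is the number of background genes with at
#' least one (propagated) annotation; query genes outside that background
#' are excluded before testing (a message reports how many). Raw p-values
#' drive the `enriched` flag; Benjamini-Hochberg q-values are reported
#' alongside but not applied to the flag.
#'
#' @param genes Character vector: the query gene list.
#' @param background Character vector of background gene ids.
#' @param annotations Propagated annotations ([propagate_annotations()]).
#' @param dag A [go_dag()].
#' @param alpha Significance level for the flag (default 0.05).
#' @return A tibble of class `go_enrichment`: `term_id`, `name`,
#'   `namespace`, `N`, `m`, `n`, `k`, `p_value`, `q_value`, `enriched`,
#'   sorted by p-value.
#' @export
enrich <- function(genes, background, annotations, dag, alpha = 0.05) {
  annotated <- unique(annotations$gene_id)
  background <- intersect(unique(background), annotated)
  N <- length(background)
  dropped <- setdiff(genes, background)
  if (length(dropped) > 0) {
    message(length(dropped), " query gene(s) outside the annotated ",
            "background excluded")
  }
  genes <- intersect(unique(genes), background)
  n <- length(genes)
  if (n == 0) {
    warning("empty query list; no enrichment computed", call. = FALSE)
    return(empty_enrichment(alpha))
  }
  ann_bg <- annotations[annotations$gene_id %in% background, ]
  m_tab <- dplyr::count(ann_bg, .data$term_id, name = "m")
  k_tab <- ann_bg[ann_bg$gene_id %in% genes, ] %>%
    dplyr::count(.data$term_id, name = "k")
  res <- dplyr::inner_join(m_tab, k_tab, by = "term_id") %>%
    dplyr::mutate(N = N, n = n)
  res$p_value <- mapply(hypergeometric_pvalue, res$N, res$m, res$n, res$k)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$enriched <- res$p_value < alpha
  res <- res %>%
    dplyr::left_join(dag$terms, by = "term_id") %>%
    dplyr::select("term_id", "name", "namespace", "N", "m", "n", "k",
                  "p_value", "q_value", "enriched") %>%
    dplyr::arrange(.data$p_value, .data$term_id)
  attr(res, "alpha") <- alpha
  class(res) <- c("go_enrichment", class(res))
  res
}

empty_enrichment <- function(alpha) {
  res <- tibble(term_id = character(), name = character(),
                namespace = character(), N = integer(), m = integer(),
                n = integer(), k = integer(), p_value = numeric(),
                q_value = numeric(), enriched = logical())
  attr(res, "alpha") <- alpha
  class(res) <- c("go_enrichment", class(res))
  res
}

#' One-row summary of an enrichment result
#' @param x A `go_enrichment`.
#' @param ... Unused.
#' @return Tibble with list size, background size, terms tested and flagged.
#' @method glance go_enrichment
#' @export
glance.go_enrichment <- function(x, ...) {
  tibble(n_terms = nrow(x),
         n_enriched = sum(x$enriched),
         n_list = if (nrow(x)) x$n[1] else 0L,
         n_background = if (nrow(x)) x$N[1] else 0L,
         alpha = attr(x, "alpha"))
}

#' Plain-tibble view of an enrichment result
#' @param x A `go_enrichment`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy go_enrichment
#' @export
tidy.go_enrichment <- function(x, ...) {
  class(x) <- setdiff(class(x), "go_enrichment")
  x
}
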