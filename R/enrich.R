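# Pathway over-representation: right-tailed Fisher / hypergeometric test of a
# query gene set against each pathway, within a stated gene universe.

#' Pathway over-representation analysis
#'
#' For each pathway, the right-tail hypergeometric probability of observing at
#' least the realised overlap between the query genes and the pathway, when
#' `pathway_size` genes are drawn from a universe containing `query_size`
#' "success" genes. This is the one-sided Fisher exact test used by pathway
#' analysis suites. Significance is called on the raw p at `alpha` (no
#' multiple-testing correction, mirroring common pathway-tool practice); a
#' BH-adjusted column is reported alongside for transparency.
#'
#' @param query_genes Character vector of query gene symbols (e.g. the
#'   DE-retained genes). Genes outside the universe are dropped with a warning.
#' @param pathways Long pathway tibble (see [read_gmt()]) or a named list of
#'   gene sets.
#' @param universe Character vector of background gene symbols. By convention
#'   this is the set of genes testable in the experiment (e.g. status-OK genes
#'   of the DE table), not the genome.
#' @param alpha Raw-p significance threshold (default 0.05, i.e.
#'   -log10 p >= 1.301).
#' @return A tibble with one row per pathway: `pathway`, `overlap`,
#'   `pathway_size`, `query_size`, `universe_size`, `p`, `neg_log10_p`,
#'   `p_bh`, `significant`; sorted by ascending p, ties broken by name.
#' @export
enrich_pathways <- function(query_genes, pathways, universe, alpha = 0.05) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  query_genes <- unique(toupper(query_genes))
  outside <- setdiff(query_genes, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene(s) outside the universe dropped: %s",
      length(outside), paste(head(outside, 5), collapse = ", ")))
    query_genes <- intersect(query_genes, universe)
  }
  sets <- if (is.data.frame(pathways)) pathway_sets(pathways) else pathways
  sets <- lapply(sets, function(g) intersect(unique(toupper(g)), universe))
  m <- length(query_genes)
  N <- length(universe)
  res <- purrr::imap(sets, function(genes, name) {
    k <- length(genes)
    x <- length(intersect(genes, query_genes))
    p <- stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE)
    tibble(
      pathway = name, overlap = x, pathway_size = k, query_size = m,
      universe_size = N, p = p
    )
  })
  out <- bind_rows(res)
  out$neg_log10_p <- -log10(out$p)
  out$p_bh <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  arrange(out, .data$p, .data$pathway)
}

#' Bar chart of pathway over-representation scores
#'
#' @param enrichment Result of [enrich_pathways()].
#' @param top Number of pathways to show (default 15).
#' @return A ggplot object: -log10(p) per pathway, significant pathways
#'   filled, with the alpha threshold line.
#' @export
plot_enrichment <- function(enrichment, top = 15) {
  df <- head(enrichment, top)
  df$pathway <- factor(df$pathway, levels = rev(df$pathway))
  thr <- -log10(0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neg_log10_p, y = .data$pathway,
    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70")) +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL, fill = "p < 0.05") +
    ggplot2::theme_minimal()
}
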