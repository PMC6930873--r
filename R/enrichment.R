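# Over-representation analysis of a query gene list against a gene-set
# collection: exact hypergeometric tail (or the more conservative EASE
# variant, which evaluates the tail with one overlap gene removed),
# Benjamini-Hochberg or Bonferroni adjustment, rich-factor scoring and
# top-N reporting.

#' Hypergeometric upper-tail p-value
#'
#' Probability of observing `k` or more query genes in a set, for a query
#' of size `n` drawn without replacement from a universe of `N` genes of
#' which `K` belong to the set. `mode = "fisher"` is the one-sided
#' Fisher/hypergeometric test, `P(X >= k)`; `mode = "ease"` is the EASE
#' score, the same tail evaluated at `k - 1` (so `k` of 0 or 1 gives
#' p = 1), the conservative variant used by the DAVID annotation tool.
#' The computation is exact (no normal approximation).
#'
#' @param k observed overlap (query genes in the set).
#' @param K set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @param mode `"fisher"` (default) or `"ease"`.
#' @return p-value in (0, 1].
#' @examples
#' hypergeom_tail(5, 5, 5, 10)  # 1/choose(10,5) = 1/252
#' @export
hypergeom_tail <- function(k, K, n, N, mode = c("fisher", "ease")) {
  mode <- match.arg(mode)
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (anyNA(c(k, K, n, N)) || k < 0 || K < 0 || n < 0 || N < 0 ||
      k > min(n, K) || K > N || n > N) {
    np_error("netpharm_validation_error",
             sprintf("invalid hypergeometric arguments k=%s K=%s n=%s N=%s",
                     k, K, n, N))
  }
  if (mode == "ease") {
    if (k <= 1L) return(1)
    k <- k - 1L
  }
  if (k == 0L) return(1)
  # P(X >= k) = upper tail of Hypergeometric(N, K, n)
  stats::phyper(k - 1L, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: `q_i` is the minimum over all
#' `p_j >= p_i` of `m * p_j / rank_j`, capped at 1, returned in the input
#' order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
adjust_bh <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    np_error("netpharm_validation_error", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' Tests each gene set for over-representation of the query. Query genes
#' outside the universe are dropped (with a logged count) before testing;
#' only sets overlapping the query (`k >= 1`) are reported and enter the
#' multiple-testing correction. Records are sorted by ascending p-value,
#' ties broken by term name. The rich factor `k / K` is the fraction of a
#' set's annotated genes hit by the query.
#'
#' @param query a [target_set] or character vector of gene identifiers.
#' @param collection a `gene_set_collection` (see [read_gmt]).
#' @param mode test variant, `"fisher"` or `"ease"`; see [hypergeom_tail].
#' @param adjust `"bh"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @return an `enrichment_table`: data frame with columns `term`, `k`,
#'   `K`, `n`, `N`, `p`, `p_adj`, `rich_factor`.
#' @export
enrich <- function(query, collection, mode = c("fisher", "ease"),
                   adjust = c("bh", "bonferroni")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  stopifnot(inherits(collection, "gene_set_collection"))
  ids <- if (inherits(query, "target_set")) query$gene_id else normalize_gene_ids(query)
  ids <- unique(ids[nzchar(ids)])
  universe <- collection$universe
  inside <- intersect(ids, universe)
  if (length(inside) < length(ids)) {
    np_log("enrich: %d query gene(s) outside the universe, dropped",
           length(ids) - length(inside))
  }
  if (!length(inside)) {
    np_error("netpharm_empty_result_error",
             "query has no genes in the annotation universe")
  }
  n <- length(inside); N <- length(universe)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]]$members, universe)
    k <- length(intersect(inside, members))
    if (k < 1L) return(NULL)
    K <- length(members)
    data.frame(term = nm, k = k, K = K, n = n, N = N,
               p = hypergeom_tail(k, K, n, N, mode = mode),
               rich_factor = k / K, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    np_error("netpharm_empty_result_error",
             "no gene set overlaps the query")
  }
  rows$p_adj <- if (adjust == "bh") adjust_bh(rows$p) else
    stats::p.adjust(rows$p, method = "bonferroni")
  rows <- rows[order(rows$p, rows$term), c("term", "k", "K", "n", "N",
                                           "p", "p_adj", "rich_factor")]
  rownames(rows) <- NULL
  structure(rows, class = c("enrichment_table", "data.frame"))
}

#' Top enriched terms
#'
#' @param records an `enrichment_table`.
#' @param n number of terms to keep.
#' @param by ranking criterion: `"p"` (ascending p-value, default) or
#'   `"count"` (descending overlap `k`); ties broken by term name.
#' @return the first `n` records after sorting.
#' @export
top_terms <- function(records, n = 20L, by = c("p", "count")) {
  by <- match.arg(by)
  stopifnot(inherits(records, "data.frame"))
  if (!is.numeric(n) || n <= 0) {
    np_error("netpharm_validation_error", "n must be a positive integer")
  }
  ord <- if (by == "p") order(records$p, records$term) else
    order(-records$k, records$term)
  out <- records[ord, , drop = FALSE]
  out <- utils::head(out, n)
  rownames(out) <- NULL
  out
}

#' Bubble-plot of an enrichment table
#'
#' Rich factor on the x-axis, one term per row, point size proportional to
#' the overlap count and colour encoding the adjusted p-value — the
#' conventional pathway-enrichment bubble chart.
#'
#' @param x an `enrichment_table`.
#' @param n_terms number of top terms (by p) to display.
#' @param ... further arguments passed to [graphics::plot].
#' @return `x`, invisibly.
#' @export
plot.enrichment_table <- function(x, n_terms = 20L, ...) {
  tab <- top_terms(x, n = n_terms, by = "p")
  tab <- tab[rev(seq_len(nrow(tab))), ]
  pal <- grDevices::colorRampPalette(c("#b2182b", "#2166ac"))(100)
  pcol <- pal[pmax(1L, ceiling(rank(tab$p_adj) / nrow(tab) * 100))]
  op <- graphics::par(mar = c(5, 12, 2, 2))
  on.exit(graphics::par(op))
  graphics::plot(tab$rich_factor, seq_len(nrow(tab)), yaxt = "n",
                 xlab = "Rich factor", ylab = "",
                 cex = 0.8 + 2.2 * tab$k / max(tab$k), pch = 19, col = pcol, ...)
  graphics::axis(2, at = seq_len(nrow(tab)), labels = tab$term, las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Write an enrichment table to TSV
#'
#' @param records an `enrichment_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
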