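# Topological feature computation: degree (DC), betweenness (BC) and
# closeness (CC) centrality under the NetworkAnalyzer conventions, i.e.
# BC normalized by (n-1)(n-2)/2 and CC the reciprocal mean shortest-path
# distance over the reachable set. Distances are unweighted hop counts.

#' Degree centrality
#'
#' DC(v) = number of edges incident to v.
#'
#' @param net undirected simple igraph network with named vertices.
#' @return named integer vector.
#' @export
degree_centrality <- function(net) {
  assert_network(net)
  d <- igraph::degree(net, loops = FALSE)
  setNames(as.integer(d), igraph::V(net)$name)
}

#' Betweenness centrality
#'
#' BC(v) is the sum over unordered node pairs `s != v != t` of the fraction
#' of shortest s-t paths passing through v, normalized by
#' `(n-1)(n-2)/2` for a network of n nodes so values lie in \[0, 1\].
#' Pairs in different components contribute 0; networks with fewer than 3
#' nodes have BC = 0 everywhere.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector in \[0, 1\].
#' @export
betweenness_centrality <- function(net) {
  assert_network(net)
  n <- igraph::vcount(net)
  nm <- igraph::V(net)$name
  if (n < 3L) return(setNames(numeric(n), nm))
  bc <- igraph::betweenness(net, directed = FALSE, normalized = TRUE)
  setNames(as.numeric(bc), nm)
}

#' Closeness centrality
#'
#' CC(v) = r_v / sum of distances from v to its reachable nodes, where r_v
#' is the number of nodes reachable from v (excluding v itself) — the
#' reciprocal of the mean shortest-path distance within v's component.
#' An isolated node has CC = 0. Computed within the reachable set, so
#' disconnected networks produce no infinite values.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector in \[0, 1\].
#' @export
closeness_centrality <- function(net) {
  assert_network(net)
  nm <- igraph::V(net)$name
  n <- igraph::vcount(net)
  if (n == 0L) return(setNames(numeric(0), character(0)))
  D <- igraph::distances(net)
  cc <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else length(d) / sum(d)
  }, numeric(1))
  setNames(cc, nm)
}

#' Compute the full topology table of a network
#'
#' One row per node with DC, BC and CC, ordered by descending DC with ties
#' broken by node identifier — a deterministic, pure function of the
#' network.
#'
#' @inheritParams degree_centrality
#' @return a `centrality_table`: data frame with columns `node`, `DC`,
#'   `BC`, `CC`.
#' @examples
#' g <- igraph::make_graph(~ A - B, B - C)
#' compute_topology(g)
#' @export
compute_topology <- function(net) {
  assert_network(net)
  dc <- degree_centrality(net)
  bc <- betweenness_centrality(net)
  cc <- closeness_centrality(net)
  tab <- data.frame(node = names(dc), DC = unname(dc),
                    BC = unname(bc[names(dc)]), CC = unname(cc[names(dc)]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$DC, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("centrality_table", "data.frame"))
}

#' Write a topology table to TSV
#'
#' BC and CC are printed to 6 decimal places; the in-memory table keeps
#' full precision.
#'
#' @param table a `centrality_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(table, path) {
  stopifnot(inherits(table, "centrality_table"))
  out <- data.frame(node = table$node, DC = table$DC,
                    BC = sprintf("%.6f", table$BC),
                    CC = sprintf("%.6f", table$CC))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a topology table from TSV
#'
#' Accepts any tab-separated table with node/DC/BC/CC columns (case
#' insensitive), e.g. an exported NetworkAnalyzer table.
#'
#' @param path TSV file with header.
#' @return a `centrality_table`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) {
    np_error("netpharm_io_error", sprintf("topology table not found: %s", path))
  }
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  lc <- tolower(names(df))
  pick <- function(keys) {
    i <- which(lc %in% keys)[1]
    if (is.na(i)) np_error("netpharm_schema_error",
                           sprintf("%s: missing column (need one of %s)",
                                   path, paste(keys, collapse = "/")))
    df[[i]]
  }
  tab <- data.frame(node = normalize_gene_ids(pick(c("node", "name", "gene", "id"))),
                    DC = as.numeric(pick(c("dc", "degree"))),
                    BC = as.numeric(pick(c("bc", "betweenness", "betweennesscentrality"))),
                    CC = as.numeric(pick(c("cc", "closeness", "closenesscentrality"))),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$DC, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("centrality_table", "data.frame"))
}
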