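# Two-stage median-threshold screening: hubs (DC strictly above twice the
# median degree) and key targets (DC, BC and CC all strictly above their
# cuts). Comparisons use full-precision medians; printing rounds for
# display only. The median of an even count is the mean of the two middle
# values (stats::median).

assert_table <- function(table) {
  if (!inherits(table, "centrality_table") || nrow(table) == 0L) {
    np_error("netpharm_validation_error",
             "a non-empty centrality_table is required")
  }
  invisible(table)
}

#' Derive screening thresholds from a topology table
#'
#' The cut-offs of the two-stage screen: `dc_cut = 2 * median(DC)`,
#' `bc_cut = median(BC)`, `cc_cut = median(CC)`, all computed over every
#' row of the table (all nodes of the network the medians describe).
#'
#' @param table a `centrality_table` (see [compute_topology]).
#' @return object of class `screening_thresholds`: list with `dc_cut`,
#'   `bc_cut`, `cc_cut` and `basis_n` (number of rows the medians were
#'   computed over).
#' @export
derive_thresholds <- function(table) {
  assert_table(table)
  structure(list(dc_cut = 2 * stats::median(table$DC),
                 bc_cut = stats::median(table$BC),
                 cc_cut = stats::median(table$CC),
                 basis_n = nrow(table)),
            class = "screening_thresholds")
}

#' @export
print.screening_thresholds <- function(x, ...) {
  cat(sprintf("Screening thresholds (over %d nodes):\n", x$basis_n))
  cat(sprintf("  DC > %s   (2 x median degree)\n", format(x$dc_cut)))
  cat(sprintf("  BC > %s\n", format(round(x$bc_cut, 6))))
  cat(sprintf("  CC > %s\n", format(round(x$cc_cut, 6))))
  invisible(x)
}

#' Select hub nodes
#'
#' Stage-1 screen: nodes whose degree is strictly greater than twice the
#' median degree of all nodes in the table.
#'
#' @param table a `centrality_table`.
#' @return a [target_set] of hubs (scored by DC), descending degree.
#' @export
select_hubs <- function(table) {
  assert_table(table)
  cut <- 2 * stats::median(table$DC)
  hubs <- table[table$DC > cut, , drop = FALSE]
  target_set(hubs$node, hubs$DC, name = "hubs")
}

#' Select key targets by the three-centrality screen
#'
#' Stage-2 screen: nodes with `DC > dc_cut`, `BC > bc_cut` and
#' `CC > cc_cut`, all strict. When `stage1` is supplied the candidates are
#' first restricted to that set (chaining the hub stage); by default all
#' table rows are candidates.
#'
#' @param table a `centrality_table`.
#' @param thresholds a `screening_thresholds`, normally derived from the
#'   same table via [derive_thresholds] (derived automatically when
#'   `NULL`). A basis size differing from the table row count triggers a
#'   warning, not an error.
#' @param stage1 optional [target_set] (e.g. hubs) restricting the
#'   candidate pool.
#' @return object of class `screening_result`: list with elements `hubs`,
#'   `key_targets` (both [target_set]s, key targets ordered by descending
#'   DC), and `thresholds`.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected")
#' igraph::V(g)$name <- c("HUB", "L1", "L2", "L3", "L4")
#' select_key_targets(compute_topology(g))
#' @export
select_key_targets <- function(table, thresholds = NULL, stage1 = NULL) {
  assert_table(table)
  if (is.null(thresholds)) thresholds <- derive_thresholds(table)
  stopifnot(inherits(thresholds, "screening_thresholds"))
  if (thresholds$basis_n != nrow(table)) {
    warning(sprintf("thresholds were derived over %d nodes but the table has %d",
                    thresholds$basis_n, nrow(table)))
  }
  cand <- table
  if (!is.null(stage1)) {
    ids <- if (inherits(stage1, "target_set")) stage1$gene_id else normalize_gene_ids(stage1)
    cand <- cand[cand$node %in% ids, , drop = FALSE]
  }
  sel <- cand[cand$DC > thresholds$dc_cut &
                cand$BC > thresholds$bc_cut &
                cand$CC > thresholds$cc_cut, , drop = FALSE]
  sel <- sel[order(-sel$DC, sel$node), , drop = FALSE]
  structure(list(hubs = select_hubs(table),
                 key_targets = target_set(sel$node, sel$DC, name = "key_targets"),
                 thresholds = thresholds),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  print(x$thresholds)
  cat(sprintf("Hubs: %d   Key targets: %d\n",
              nrow(x$hubs), nrow(x$key_targets)))
  if (nrow(x$key_targets)) {
    cat("Top key targets (by degree):\n")
    print(as.data.frame(utils::head(x$key_targets, 10L)))
  }
  invisible(x)
}
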