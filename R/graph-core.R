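# Seed-expanded subnetwork construction and network merging.

assert_network <- function(net, arg = "net") {
  if (!igraph::is_igraph(net) || is.null(igraph::V(net)$name)) {
    np_error("netpharm_validation_error",
             sprintf("%s must be an igraph object with named vertices", arg))
  }
  if (igraph::is_directed(net) || igraph::any_multiple(net) ||
      any(igraph::which_loop(net))) {
    np_error("netpharm_validation_error",
             sprintf("%s must be an undirected simple graph", arg))
  }
  invisible(net)
}

#' Expand a seed target set to its neighbourhood subnetwork
#'
#' Builds the subnetwork a PPI plugin would draw around a target list: the
#' seeds found in the background interactome plus every node within
#' `depth` hops of a seed, with *all* background edges among those nodes
#' (the induced subgraph, so neighbour-neighbour edges are retained).
#' Vertices carry a `role` attribute: `"seed"` for seeds present in the
#' background, `"neighbor"` otherwise — the direct vs indirect target
#' distinction of a network-pharmacology map. Seeds absent from the
#' background are logged and excluded rather than added as isolated nodes
#' (isolated nodes have zero degree and undefined closeness and would
#' distort the median-based screening downstream).
#'
#' @param seeds a [target_set] or character vector of seed identifiers.
#' @param background background interactome (undirected simple igraph with
#'   named vertices).
#' @param depth neighbourhood order; default 1 (seeds + direct
#'   interactors).
#' @return igraph subnetwork of `background` with a `role` vertex
#'   attribute.
#' @export
expand_seed_network <- function(seeds, background, depth = 1L) {
  assert_network(background, "background")
  ids <- if (inherits(seeds, "target_set")) seeds$gene_id else normalize_gene_ids(seeds)
  ids <- unique(ids[nzchar(ids)])
  if (!length(ids)) {
    np_error("netpharm_validation_error", "seed set is empty")
  }
  present <- intersect(ids, igraph::V(background)$name)
  if (!length(present)) {
    np_error("netpharm_empty_result_error",
             "no seed is present in the background interactome")
  }
  if (length(present) < length(ids)) {
    np_log("expand_seed_network: %d/%d seed(s) absent from background, excluded",
           length(ids) - length(present), length(ids))
  }
  nodes <- igraph::ego(background, order = depth, nodes = present)
  nodes <- unique(names(unlist(nodes)))
  sub <- igraph::induced_subgraph(background, vids = nodes)
  igraph::V(sub)$role <- ifelse(igraph::V(sub)$name %in% present, "seed", "neighbor")
  sub
}

#' Merge two networks
#'
#' Default semantics follow an intersection merge: shared nodes and shared
#' edges only (`mode = "intersection"`). The alternative
#' `"induced-union"` keeps the shared nodes but every edge either parent
#' has between them. A node's role is `"seed"` if it is a seed in either
#' parent.
#'
#' @param a,b igraph networks (optionally with `role` vertex attributes).
#' @param mode `"intersection"` (shared nodes, shared edges; default) or
#'   `"induced-union"` (shared nodes, union of parent edges among them).
#' @return merged igraph network; an empty intersection is a valid result.
#' @export
intersect_networks <- function(a, b, mode = c("intersection", "induced-union")) {
  mode <- match.arg(mode)
  assert_network(a, "a"); assert_network(b, "b")
  common <- intersect(igraph::V(a)$name, igraph::V(b)$name)
  sub_a <- igraph::induced_subgraph(a, vids = common)
  sub_b <- igraph::induced_subgraph(b, vids = common)
  ea <- edge_key(sub_a); eb <- edge_key(sub_b)
  keys <- if (mode == "intersection") intersect(ea, eb) else union(ea, eb)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  from <- vapply(parts, `[`, character(1), 1L)
  to <- vapply(parts, `[`, character(1), 2L)
  g <- new_ppi_network(from, to, extra_nodes = common)
  role_a <- role_of(a); role_b <- role_of(b)
  nm <- igraph::V(g)$name
  igraph::V(g)$role <- ifelse(role_a[nm] %in% "seed" | role_b[nm] %in% "seed",
                              "seed", "neighbor")
  g
}

# canonical order-independent edge keys
edge_key <- function(g) {
  el <- igraph::as_edgelist(g)
  if (!nrow(el)) return(character(0))
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
}

role_of <- function(g) {
  r <- igraph::V(g)$role
  if (is.null(r)) r <- rep("neighbor", igraph::vcount(g))
  setNames(r, igraph::V(g)$name)
}
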