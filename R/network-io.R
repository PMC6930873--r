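# Reading and writing PPI networks. Networks are undirected simple igraph
# objects with normalized vertex names; self-loops and duplicate edges in
# the input are dropped (with a logged count), matching the untyped
# simple-graph model of a PPI interactome.

new_ppi_network <- function(edges_from, edges_to, extra_nodes = character()) {
  from <- normalize_gene_ids(edges_from)
  to <- normalize_gene_ids(edges_to)
  nodes <- unique(c(from, to, normalize_gene_ids(extra_nodes)))
  nodes <- nodes[nzchar(nodes)]
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  n_before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dropped <- n_before - igraph::ecount(g)
  if (dropped > 0) {
    np_log("read_edge_list: dropped %d self-loop/duplicate edge(s)", dropped)
  }
  g
}

#' Read a PPI network from an edge-list file
#'
#' Supported dialects:
#' \describe{
#'   \item{`sif`}{Cytoscape simple-interaction format: whitespace-delimited
#'     `source interaction target [target ...]`. The interaction-type token
#'     is ignored (PPI edges are untyped); a line with a single token
#'     declares an isolated node.}
#'   \item{`tsv`}{two tab-separated columns, one edge per line, no header.}
#'   \item{`graphml`}{GraphML, via igraph.}
#' }
#' Node identifiers are normalized (trimmed, uppercased); self-loops and
#' duplicate undirected edges are dropped with a logged count.
#'
#' @param path file path.
#' @param format `"sif"`, `"tsv"` or `"graphml"`; default guesses from the
#'   file extension.
#' @return an undirected simple igraph object with named vertices.
#' @export
read_edge_list <- function(path, format = c("auto", "sif", "tsv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    np_error("netpharm_io_error", sprintf("network file not found: %s", path))
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", tsv = "tsv", txt = "tsv",
                     graphml = "graphml", xml = "graphml",
                     np_error("netpharm_usage_error",
                              sprintf("cannot guess format from extension '.%s'; pass format=", ext)))
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    if (is.null(igraph::V(g)$name)) {
      np_error("netpharm_parse_error",
               sprintf("graphml file %s has no vertex 'name' attribute", path))
    }
    igraph::V(g)$name <- normalize_gene_ids(igraph::V(g)$name)
    return(new_ppi_network(igraph::as_edgelist(g)[, 1], igraph::as_edgelist(g)[, 2],
                           extra_nodes = igraph::V(g)$name))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  from <- character(0); to <- character(0); isolated <- character(0)
  if (format == "sif") {
    for (i in seq_along(lines)) {
      tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(tok) == 1L) {
        isolated <- c(isolated, tok)
      } else if (length(tok) >= 3L) {
        from <- c(from, rep(tok[1], length(tok) - 2L))
        to <- c(to, tok[-(1:2)])
      } else {
        np_error("netpharm_parse_error",
                 sprintf("%s line %d: SIF line needs 1 or >=3 tokens, found %d",
                         path, lineno[i], length(tok)))
      }
    }
  } else { # tsv
    for (i in seq_along(lines)) {
      tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      tok <- trimws(tok)
      if (length(tok) < 2L || !nzchar(tok[1]) || !nzchar(tok[2])) {
        np_error("netpharm_parse_error",
                 sprintf("%s line %d: expected two tab-separated node ids", path, lineno[i]))
      }
      from <- c(from, tok[1]); to <- c(to, tok[2])
    }
  }
  new_ppi_network(from, to, extra_nodes = isolated)
}

#' Write a PPI network to an edge-list file
#'
#' Counterpart of [read_edge_list]; isolated nodes are preserved in the
#' `sif` and `graphml` dialects (the 2-column `tsv` dialect cannot express
#' them and raises an error if any are present).
#'
#' @param net an igraph network with named vertices.
#' @param path output path.
#' @param format `"sif"`, `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, format = c("sif", "tsv", "graphml")) {
  format <- match.arg(format)
  stopifnot(igraph::is_igraph(net))
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(net)
  iso <- igraph::V(net)$name[igraph::degree(net) == 0]
  if (format == "sif") {
    out <- character(0)
    if (nrow(el)) out <- paste(el[, 1], "pp", el[, 2])
    out <- c(out, iso)
    writeLines(out, path)
  } else {
    if (length(iso)) {
      np_error("netpharm_usage_error",
               "tsv edge list cannot represent isolated nodes; use sif or graphml")
    }
    writeLines(paste(el[, 1], el[, 2], sep = "\t"), path)
  }
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-delimited gene-set format: one set per line, fields
#' `name`, `description`, then member genes. Member identifiers are
#' normalized and within-set duplicates dropped; the universe defaults to
#' the union of all members.
#'
#' @param path GMT file path.
#' @return an object of class `gene_set_collection`: a list with elements
#'   `sets` (named list of `list(description, members)`) and `universe`
#'   (character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    np_error("netpharm_io_error", sprintf("GMT file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(tok) < 3L) {
      np_error("netpharm_parse_error",
               sprintf("%s line %d: GMT line needs >=3 tab-separated fields", path, i))
    }
    nm <- trimws(tok[1])
    if (nm %in% names(sets)) {
      np_error("netpharm_schema_error",
               sprintf("%s: duplicate set name '%s'", path, nm))
    }
    members <- unique(normalize_gene_ids(tok[-(1:2)]))
    members <- members[nzchar(members)]
    sets[[nm]] <- list(description = tok[2], members = members)
  }
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#'
#' @param sets named list; each element a `list(description, members)` or a
#'   plain character vector of members.
#' @param universe optional explicit background gene universe; defaults to
#'   the union of all set members. Set members outside a supplied universe
#'   are an error.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), !anyDuplicated(names(sets)))
  sets <- lapply(sets, function(s) {
    if (is.character(s)) s <- list(description = "", members = s)
    s$members <- unique(normalize_gene_ids(s$members))
    s
  })
  all_members <- unique(unlist(lapply(sets, `[[`, "members"), use.names = FALSE))
  if (is.null(universe)) {
    universe <- sort(all_members)
  } else {
    universe <- unique(normalize_gene_ids(universe))
    outside <- setdiff(all_members, universe)
    if (length(outside)) {
      np_error("netpharm_validation_error",
               sprintf("%d set member(s) outside the supplied universe (e.g. %s)",
                       length(outside), outside[1]))
    }
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, function(s) length(s$members), integer(1))
  cat(sprintf("Gene-set collection: %d set(s), universe of %d gene(s)\n",
              length(x$sets), length(x$universe)))
  cat(sprintf("  set sizes: min %d, median %s, max %d\n",
              min(sizes), format(stats::median(sizes)), max(sizes)))
  invisible(x)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a `gene_set_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    paste(c(nm, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
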