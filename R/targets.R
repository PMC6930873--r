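# Target sets: named collections of normalized gene identifiers with
# optional non-negative fit scores.

#' Normalize gene identifiers
#'
#' Canonical form used throughout the package: leading/trailing whitespace
#' trimmed, then uppercased. Deterministic and idempotent, so identifiers
#' coming from mixed sources (official symbols, UniProt accessions) can be
#' intersected reliably.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of normalized identifiers.
#' @examples
#' normalize_gene_ids(c(" tp53", "Akt1 "))
#' @export
normalize_gene_ids <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct a target set
#'
#' A target set is the package's container for a drug- or disease-target
#' list: unique normalized gene identifiers with optional scores (e.g. the
#' pharmacophore fit score of a reverse-docking prediction). Duplicate
#' identifiers collapse keeping the maximum score, mirroring "best fit"
#' ranking semantics.
#'
#' @param gene_ids character vector of identifiers (normalized internally).
#' @param scores optional numeric vector of finite, non-negative scores,
#'   recycled checks apply; `NULL` for an unscored set.
#' @param name label for the set.
#' @return object of class `target_set`: a data frame with columns
#'   `gene_id` and `score` (`NA` when unscored) and a `set_name` attribute.
#' @examples
#' target_set(c("tp53", "TP53", "akt1"), c(5.1, 4.0, 6.2), name = "drug")
#' @export
target_set <- function(gene_ids, scores = NULL, name = "targets") {
  ids <- normalize_gene_ids(gene_ids)
  keep <- nzchar(ids) & !is.na(ids)
  ids <- ids[keep]
  if (is.null(scores)) {
    sc <- rep(NA_real_, length(ids))
  } else {
    sc <- as.numeric(scores)[keep]
    bad <- !is.na(sc) & (!is.finite(sc) | sc < 0)
    if (any(bad)) {
      np_error("netpharm_validation_error",
               sprintf("scores must be finite and >= 0 (offending ids: %s)",
                       paste(ids[bad], collapse = ", ")))
    }
  }
  # collapse duplicates keeping the maximum score
  if (anyDuplicated(ids)) {
    ord <- order(ids, -xtfrm(ifelse(is.na(sc), -Inf, sc)))
    ids_o <- ids[ord]; sc_o <- sc[ord]
    first <- !duplicated(ids_o)
    ids <- ids_o[first]; sc <- sc_o[first]
  }
  out <- data.frame(gene_id = ids, score = sc, stringsAsFactors = FALSE)
  out <- out[order(-xtfrm(ifelse(is.na(out$score), -Inf, out$score)), out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, set_name = as.character(name)[1],
            class = c("target_set", "data.frame"))
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("Target set '%s': %d gene(s)%s\n",
              attr(x, "set_name"), nrow(x),
              if (all(is.na(x$score))) "" else " (scored)"))
  print(as.data.frame(utils::head(x, 10L)), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Read a target list from a TSV file
#'
#' Expects a tab-separated file with a header line. Identifiers are
#' normalized and duplicates collapse keeping the maximum score.
#'
#' @param path file path.
#' @param id_column name of the identifier column; defaults to the first
#'   column.
#' @param score_column optional name of a numeric score column; `NULL` for
#'   an unscored list.
#' @param name label for the resulting set; defaults to the file base name.
#' @return a [target_set].
#' @export
read_target_list <- function(path, id_column = NULL, score_column = NULL,
                             name = NULL) {
  if (!file.exists(path)) {
    np_error("netpharm_io_error", sprintf("target list not found: %s", path))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(id_column)) id_column <- names(df)[1]
  if (!id_column %in% names(df)) {
    np_error("netpharm_schema_error",
             sprintf("id column '%s' missing from %s (columns: %s)",
                     id_column, path, paste(names(df), collapse = ", ")))
  }
  if (!is.null(score_column) && !score_column %in% names(df)) {
    np_error("netpharm_schema_error",
             sprintf("score column '%s' missing from %s", score_column, path))
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  scores <- if (is.null(score_column)) NULL else as.numeric(df[[score_column]])
  target_set(df[[id_column]], scores, name = name)
}

#' Write a target set to a TSV file
#'
#' @param targets a [target_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_target_list <- function(targets, path) {
  stopifnot(inherits(targets, "target_set"))
  df <- as.data.frame(targets)
  if (all(is.na(df$score))) df$score <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a scored target set by minimum fit score
#'
#' Keeps entries whose score is *strictly* greater than `min_score` (the
#' usual reading of a published cut such as "fit score > 4.5"), ordered by
#' descending score.
#'
#' @param targets a scored [target_set]; an unscored entry is an error.
#' @param min_score numeric threshold; entries with `score > min_score` are
#'   kept.
#' @return a [target_set].
#' @examples
#' ts <- target_set(c("A", "B"), c(4.5, 4.6))
#' filter_targets_by_score(ts, 4.5)  # keeps only B
#' @export
filter_targets_by_score <- function(targets, min_score) {
  stopifnot(inherits(targets, "target_set"), is.numeric(min_score))
  if (anyNA(targets$score)) {
    np_error("netpharm_validation_error",
             sprintf("unscored entries cannot be score-filtered: %s",
                     paste(targets$gene_id[is.na(targets$score)], collapse = ", ")))
  }
  keep <- targets$score > min_score
  out <- targets[keep, , drop = FALSE]
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, set_name = attr(targets, "set_name"),
            class = class(targets))
}

#' Read an identifier map from a two-column TSV file
#'
#' The map translates raw identifiers (e.g. UniProt accessions) to official
#' gene symbols; it is the offline stand-in for a UniProtKB lookup.
#' Many-to-one mappings are allowed; both columns are normalized.
#'
#' @param path TSV file; first column raw id, second column symbol. A header
#'   is detected and skipped when the first line repeats no data pattern
#'   (always treated as header when its fields are `from`/`to` or similar);
#'   plain two-column files without header also parse.
#' @return a named character vector (`names` = raw ids, values = symbols)
#'   of class `id_map`.
#' @export
read_id_map <- function(path) {
  if (!file.exists(path)) {
    np_error("netpharm_io_error", sprintf("id map not found: %s", path))
  }
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    np_error("netpharm_schema_error",
             sprintf("id map %s must have two tab-separated columns", path))
  }
  # drop a header line if present
  if (tolower(df[1, 1]) %in% c("from", "raw", "id", "raw_id", "accession")) {
    df <- df[-1, , drop = FALSE]
  }
  from <- normalize_gene_ids(df[[1]])
  to <- normalize_gene_ids(df[[2]])
  ok <- nzchar(from) & nzchar(to)
  structure(setNames(to[ok], from[ok]), class = "id_map")
}

#' Translate a target set through an identifier map
#'
#' Identifiers found in the map are replaced by their official symbols;
#' merges arising from many-to-one mappings collapse keeping the maximum
#' score. Unmapped identifiers are handled per `on_missing`.
#'
#' @param targets a [target_set].
#' @param map an `id_map` (see [read_id_map]) or named character vector.
#' @param on_missing one of `"keep"` (pass unmapped ids through unchanged,
#'   default), `"drop"` (remove them, logging the count), `"error"`.
#' @return a [target_set] with translated identifiers.
#' @export
apply_id_map <- function(targets, map, on_missing = c("keep", "drop", "error")) {
  stopifnot(inherits(targets, "target_set"))
  on_missing <- match.arg(on_missing)
  map <- setNames(normalize_gene_ids(map), normalize_gene_ids(names(map)))
  hit <- targets$gene_id %in% names(map)
  if (any(!hit)) {
    missing_ids <- targets$gene_id[!hit]
    if (on_missing == "error") {
      np_error("netpharm_mapping_error",
               sprintf("unmapped identifiers: %s", paste(missing_ids, collapse = ", ")),
               ids = missing_ids)
    }
    np_log("apply_id_map: %d identifier(s) not in map (%s)",
           length(missing_ids), on_missing)
  }
  ids <- targets$gene_id
  ids[hit] <- unname(map[ids[hit]])
  keep <- hit | (on_missing == "keep")
  target_set(ids[keep], if (all(is.na(targets$score))) NULL else targets$score[keep],
             name = attr(targets, "set_name"))
}
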