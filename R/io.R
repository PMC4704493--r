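# Readers and writers for the delimited-table formats the pipeline
# consumes and emits, plus GraphML export of cluster hierarchies.
# Default dialect is TSV (UTF-8, "." decimal); CSV is accepted via the
# `dialect` argument. Empty cells and "NA" are read as missing.

read_delim_dialect <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    ms_validation_error(sprintf("file does not exist: %s", path))
  }
  sep <- if (dialect == "tsv") "\t" else ","
  utils::read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""),
                    fileEncoding = "UTF-8")
}

write_delim_dialect <- function(df, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a per-well screen table into screen plates
#'
#' @param path Path to a delimited file whose header names the well-record
#'   fields: plate_id, cell_line, replicate, row, column, mimic_id,
#'   raw_lum.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @param normalized Mark the plates as already row-median normalized.
#' @return A named list of \code{\link{screen_plate}} objects.
#' @export
read_well_table <- function(path, dialect = c("tsv", "csv"),
                            normalized = FALSE) {
  df <- read_delim_dialect(path, dialect)
  as_screen_plates(df, normalized = normalized)
}

#' Write screen plates (or a well table) to a delimited file
#'
#' @param x A list of \code{\link{screen_plate}} objects or a well table
#'   data frame.
#' @param path Output path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return The path, invisibly.
#' @export
write_well_table <- function(x, path, dialect = c("tsv", "csv")) {
  df <- if (is.data.frame(x)) validate_well_table(x) else as_well_table(x)
  write_delim_dialect(as.data.frame(df), path, dialect)
}

#' Write a z-score matrix to a labeled delimited file
#'
#' Layout: first column \code{mimic_id}, remaining columns one per cell
#' line. Missing values are written as the sentinel \code{NA}.
#'
#' @param m A \code{\link{zscore_matrix}} (or plain labeled matrix).
#' @param path Output path.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return The path, invisibly.
#' @export
write_zscore_matrix <- function(m, path, dialect = c("tsv", "csv")) {
  if (!is.matrix(m)) ms_validation_error("m must be a matrix")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    ms_integrity_error("labels must be unique")
  }
  df <- data.frame(mimic_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  # full precision so the round trip is lossless to <= 1e-12
  old <- options(digits = 17); on.exit(options(old))
  write_delim_dialect(df, path, dialect)
}

#' Read a z-score matrix from a labeled delimited file
#'
#' @param path Input path (first column mimic ids, header names the cell
#'   lines).
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @return A \code{\link{zscore_matrix}}.
#' @export
read_zscore_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    ms_validation_error(sprintf("file does not exist: %s", path))
  }
  sep <- if (dialect == "tsv") "\t" else ","
  # read as character first so non-numeric cells can be located precisely
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""),
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2L) ms_schema_error("matrix file needs id + value columns")
  ids <- df[[1L]]
  vals <- df[-1L]
  parsed <- lapply(seq_along(vals), function(j) {
    raw <- vals[[j]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw))
    if (length(bad) > 0L) {
      ms_parse_error(sprintf(
        "non-numeric cell '%s' at row %d (mimic '%s'), column '%s'",
        raw[bad[1L]], bad[1L], ids[bad[1L]], names(vals)[j]),
        row = bad[1L], column = names(vals)[j])
    }
    num
  })
  z <- do.call(cbind, parsed)
  rownames(z) <- ids
  colnames(z) <- names(vals)
  zscore_matrix(z)
}

#' Export a cluster hierarchy as a GraphML network
#'
#' One node per clustered item; a node attribute per hierarchy level
#' records the composed cluster membership (exemplar label) at that level,
#' and directed edges connect each item to its exemplar at each level
#' (self-edges mark exemplars). The file can be opened directly in
#' Cytoscape or re-imported with \code{\link{import_cluster_network}}.
#'
#' @param h A \code{\link{hierarchical_ap}} result (class
#'   \code{"cluster_hierarchy"}).
#' @param path Output path for the GraphML file.
#' @return The path, invisibly.
#' @export
export_cluster_network <- function(h, path) {
  if (!inherits(h, "cluster_hierarchy")) {
    ms_validation_error("h must be a cluster_hierarchy")
  }
  memb <- h$membership
  if (is.null(memb) || nrow(memb) == 0L) {
    ms_empty_error("empty hierarchy: nothing to export")
  }
  items <- rownames(memb)
  g <- igraph::make_empty_graph(n = length(items), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = items)
  for (l in seq_len(ncol(memb))) {
    g <- igraph::set_vertex_attr(g, sprintf("level%d_exemplar", l),
                                 value = memb[, l])
  }
  edges <- character(0)
  elevel <- integer(0)
  for (l in seq_len(ncol(memb))) {
    edges <- c(edges, as.vector(rbind(items, memb[, l])))
    elevel <- c(elevel, rep.int(l, length(items)))
  }
  g <- igraph::add_edges(g, edges, attr = list(level = elevel))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Re-import membership labels from an exported cluster network
#'
#' @param path A GraphML file written by
#'   \code{\link{export_cluster_network}}.
#' @return A data frame with column \code{item} and one
#'   \code{levelL_exemplar} column per exported level.
#' @export
import_cluster_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  attrs <- igraph::vertex_attr(g)
  lv <- grep("^level[0-9]+_exemplar$", names(attrs), value = TRUE)
  lv <- lv[order(as.integer(sub("^level([0-9]+)_exemplar$", "\\1", lv)))]
  out <- data.frame(item = attrs$name, stringsAsFactors = FALSE)
  for (a in lv) out[[a]] <- attrs[[a]]
  out
}
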