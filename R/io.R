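#' Read a traces CSV into a trace matrix
#'
#' The file holds one row per cell and one column per time point. Two layout
#' variations are tolerated and auto-detected:
#' \itemize{
#'   \item a header row is assumed present when any field of the first row
#'     beyond the first column is non-numeric (e.g. `"t1"`); the first column
#'     is ignored in this check because it may hold cell ids in every row. A
#'     first row made entirely of numbers is treated as data, so purely
#'     numeric time-index headers are not distinguishable from a data row and
#'     should be omitted;
#'   \item a leading id column is assumed when any entry of the first column
#'     is non-numeric; otherwise cell ids are synthesized as the row index
#'     (`"1"`, `"2"`, ...).
#' }
#' Missing or non-numeric body values are rejected with the offending row and
#' column named; traces are never imputed.
#'
#' @param path path to a comma-delimited UTF-8 file.
#' @param frame_interval_s seconds between frames (required; event rates and
#'   spectra are meaningless without it).
#' @param transpose set `TRUE` when the file holds cells in columns instead of
#'   rows.
#' @return A [trace_matrix()].
#' @export
read_traces <- function(path, frame_interval_s, transpose = FALSE) {
  if (!file.exists(path)) stop("traces file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0L || ncol(raw) == 0L) stop("traces file is empty: ", path, call. = FALSE)
  is_num <- function(v) {
    v <- trimws(v)
    nzchar(v) & !is.na(suppressWarnings(as.numeric(v)))
  }
  # header detection ignores the first column, which may hold cell ids in
  # every row; a purely numeric first row is always treated as data
  first_row_body <- unlist(raw[1L, -1L, drop = FALSE], use.names = FALSE)
  has_header <- length(first_row_body) > 0L && !all(is_num(first_row_body))
  body <- if (has_header) raw[-1L, , drop = FALSE] else raw
  if (nrow(body) == 0L) stop("traces file contains a header but no data rows", call. = FALSE)
  has_ids <- !all(is_num(body[[1L]]))
  ids <- if (has_ids) trimws(body[[1L]]) else as.character(seq_len(nrow(body)))
  num_part <- if (has_ids) body[, -1L, drop = FALSE] else body
  if (ncol(num_part) == 0L) stop("traces file has no numeric columns", call. = FALSE)
  vals <- matrix(NA_real_, nrow(num_part), ncol(num_part))
  for (j in seq_len(ncol(num_part))) {
    col <- trimws(num_part[[j]])
    v <- suppressWarnings(as.numeric(col))
    v[!nzchar(col)] <- NA_real_
    bad <- which(is.na(v))
    if (length(bad))
      stop("missing or non-numeric value at data row ", bad[1L], ", column ",
           j + has_ids, " of ", path, call. = FALSE)
    vals[, j] <- v
  }
  if (isTRUE(transpose)) {
    vals <- t(vals)
    ids <- as.character(seq_len(nrow(vals)))
  }
  if (ncol(vals) < 2L)
    stop("traces must contain at least two time points (found ", ncol(vals), ")",
         call. = FALSE)
  trace_matrix(vals, ids, frame_interval_s)
}

#' Read a cell coordinate table
#'
#' Expects a header containing columns `X`, `Y` and `Cell`, with an optional
#' `Label` column marking subset membership (column names are matched
#' case-insensitively). Extra columns are ignored.
#'
#' @param path path to a CSV file.
#' @return A [cell_table()]; `label` is `NA` for every cell when the file has
#'   no Label column.
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) stop("cell table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                        strip.white = TRUE, check.names = FALSE)
  nm <- tolower(trimws(names(df)))
  pick <- function(col) {
    i <- which(nm == col)
    if (length(i) == 0L) return(NULL)
    df[[i[1L]]]
  }
  x <- pick("x"); y <- pick("y"); cell <- pick("cell")
  missing_cols <- c("X", "Y", "Cell")[c(is.null(x), is.null(y), is.null(cell))]
  if (length(missing_cols))
    stop("cell table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  cell_table(cell = cell, x = x, y = y, label = pick("label"))
}

#' Align a cell table to the trace matrix row order
#'
#' Identifiers are compared as whitespace-trimmed strings. The two id sets
#' must coincide exactly; any mismatch aborts with the symmetric difference
#' listed. The returned table is reordered to the trace row order, so
#' downstream results are invariant to the row order of the coordinate file.
#'
#' @param traces a [trace_matrix()] (or derived container with `cell_ids`).
#' @param cells a [cell_table()].
#' @return The reordered `cell_table`.
#' @export
align_cells <- function(traces, cells) {
  tid <- traces$cell_ids
  cid <- cells$cell
  only_t <- setdiff(tid, cid)
  only_c <- setdiff(cid, tid)
  if (length(only_t) || length(only_c))
    stop("cell ids do not match between traces and cell table; ",
         "only in traces: {", paste(only_t, collapse = ", "), "}; ",
         "only in cell table: {", paste(only_c, collapse = ", "), "}",
         call. = FALSE)
  out <- cells[match(tid, cid), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cell_table", "data.frame")
  out
}

#' Write a functional graph to disk
#'
#' @param g a [build_graph()] result.
#' @param path output file path.
#' @param format `"graphml"` (nodes with coordinates, labels and any community
#'   assignment; weighted edges) or `"edge_csv"` (flat `source,target,weight`
#'   table; node attributes are not representable in this format).
#' @return Invisibly, `path`.
#' @seealso [read_graph_file()] for the graphml round trip.
#' @export
write_graph <- function(g, path, format = c("graphml", "edge_csv")) {
  stopifnot(inherits(g, "functional_graph"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g$graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g$graph, names = TRUE)
    w <- igraph::E(g$graph)$weight
    utils::write.csv(
      data.frame(source = el[, 1L], target = el[, 2L],
                 weight = if (is.null(w)) rep(1, nrow(el)) else w,
                 stringsAsFactors = FALSE),
      path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a graphml file written by [write_graph()]
#'
#' @param path a graphml file.
#' @return A `functional_graph`; the threshold is recovered from the stored
#'   graph attribute when present.
#' @export
read_graph_file <- function(path) {
  gr <- igraph::read_graph(path, format = "graphml")
  theta <- igraph::graph_attr(gr, "theta")
  structure(list(graph = gr, theta = if (is.null(theta)) NA_real_ else theta),
            class = "functional_graph")
}

#' Write a trace matrix (or derived container) to CSV
#'
#' Emits the cells-in-rows dialect accepted by [read_traces()]: a leading
#' `Cell` id column, no time header.
#'
#' @param t a `trace_matrix`, `normalized_traces` or `binary_raster`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(t, path) {
  df <- data.frame(Cell = t$cell_ids, t$values, stringsAsFactors = FALSE,
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' Write a cell table to CSV in the `X,Y,Cell,Label` dialect
#'
#' @param cells a [cell_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cells <- function(cells, path) {
  df <- data.frame(X = cells$x, Y = cells$y, Cell = cells$cell,
                   Label = ifelse(is.na(cells$label), "", cells$label),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
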