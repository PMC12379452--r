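#' @title Core containers for calcium-imaging trace analysis
#' @description
#' `trace_matrix` holds a cells-by-time fluorescence matrix together with the
#' cell identifiers and the acquisition frame interval. All downstream stages
#' (normalization, binarization, connectivity, spectra) operate on this
#' container or on containers derived from it, so shapes and identifiers are
#' validated once, here.
#' @name cinet-types
NULL

#' Construct a trace matrix
#'
#' @param values numeric matrix, rows = cells, columns = time points
#'   (fluorescence, arbitrary units).
#' @param cell_ids character vector of unique cell identifiers, one per row.
#'   Defaults to the row index as a string.
#' @param frame_interval_s positive scalar, seconds between consecutive frames.
#' @return An object of class `trace_matrix` with fields `values`, `cell_ids`
#'   and `frame_interval_s`.
#' @export
trace_matrix <- function(values, cell_ids = NULL, frame_interval_s) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(nrow(values)))
  cell_ids <- trimws(as.character(cell_ids))
  if (nrow(values) < 1L) stop("trace matrix must contain at least one cell", call. = FALSE)
  if (ncol(values) < 2L) stop("trace matrix must contain at least two time points", call. = FALSE)
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids), ") does not match number of rows (",
         nrow(values), ")", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell ids: ", paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite trace value at cell '", cell_ids[bad[1L]], "', time point ",
         bad[2L], call. = FALSE)
  }
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      !is.finite(frame_interval_s) || frame_interval_s <= 0)
    stop("frame_interval_s must be a positive scalar (seconds per frame)", call. = FALSE)
  rownames(values) <- cell_ids
  structure(list(values = values, cell_ids = cell_ids,
                 frame_interval_s = as.numeric(frame_interval_s)),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat("<trace_matrix> ", nrow(x$values), " cells x ", ncol(x$values),
      " time points, frame interval ", x$frame_interval_s, " s\n", sep = "")
  invisible(x)
}

#' Construct a cell table
#'
#' Spatial coordinates and optional subset labels for each cell. Labels mark a
#' subset of interest (e.g. cells carrying a second fluorescent reporter);
#' when no label information exists the `label` column is `NA` throughout.
#'
#' @param cell character vector of cell identifiers.
#' @param x,y numeric image coordinates.
#' @param label optional character vector of subset labels (`NA` = unlabeled).
#' @return A `data.frame` of class `cell_table` with columns `cell`, `x`, `y`,
#'   `label`.
#' @export
cell_table <- function(cell, x, y, label = NULL) {
  cell <- trimws(as.character(cell))
  if (anyDuplicated(cell))
    stop("duplicate cell ids in cell table: ",
         paste(unique(cell[duplicated(cell)]), collapse = ", "), call. = FALSE)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(cell) || length(y) != length(cell))
    stop("cell, x and y must have equal length", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("cell coordinates must be finite", call. = FALSE)
  if (is.null(label)) label <- rep(NA_character_, length(cell))
  label <- as.character(label)
  label[!is.na(label) & trimws(label) == ""] <- NA_character_
  df <- data.frame(cell = cell, x = x, y = y, label = label,
                   stringsAsFactors = FALSE)
  class(df) <- c("cell_table", "data.frame")
  df
}

#' @export
print.cell_table <- function(x, ...) {
  nlab <- sum(!is.na(x$label))
  cat("<cell_table> ", nrow(x), " cells, ", nlab, " labeled\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

# internal: shared skeleton for trace-shaped derived containers
new_trace_like <- function(values, template, class, extra = list()) {
  rownames(values) <- template$cell_ids
  structure(c(list(values = values, cell_ids = template$cell_ids,
                   frame_interval_s = template$frame_interval_s), extra),
            class = class)
}

#' @export
print.normalized_traces <- function(x, ...) {
  cat("<normalized_traces> ", nrow(x$values), " cells x ", ncol(x$values),
      " time points, method = ", x$method, "\n", sep = "")
  invisible(x)
}

#' @export
print.binary_raster <- function(x, ...) {
  cat("<binary_raster> ", nrow(x$values), " cells x ", ncol(x$values),
      " time points, ", sum(x$values), " active samples (rule: ",
      x$threshold_spec$rule, ")\n", sep = "")
  invisible(x)
}

# internal: accept either a trace-shaped object or bare matrix-bearing list
trace_values <- function(obj) {
  if (is.list(obj) && !is.null(obj$values)) obj$values
  else if (is.matrix(obj)) obj
  else stop("expected a trace-like object with a 'values' matrix", call. = FALSE)
}
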