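#' Percentage of active cells over time
#'
#' At each frame, the fraction of cells whose binarized state is 1, as a
#' percentage: `100 * (1/N) * sum_i x_bin[i, t]`. Synchronized population
#' events appear as peaks of this trace.
#'
#' @param b a `binary_raster`.
#' @return An `activity_trace`: list with `percent_active` (length `n_time`,
#'   in `[0, 100]`) and `time_s` (seconds from recording start,
#'   `(t - 1) * frame_interval_s`).
#' @export
active_percentage <- function(b) {
  stopifnot(inherits(b, "binary_raster"))
  pct <- 100 * colMeans(b$values)
  structure(list(percent_active = as.numeric(pct),
                 time_s = (seq_len(ncol(b$values)) - 1) * b$frame_interval_s),
            class = "activity_trace")
}

#' Mean calcium-event frequency (events per minute)
#'
#' An event is a rising edge of the binarized trace: a 0-to-1 transition, with
#' a 1 in the first frame counting as an onset. Each cell's rate is its onset
#' count divided by the recording duration `n_time * frame_interval_s / 60`
#' minutes; the returned value is the mean rate over the selected cells.
#'
#' `mode = "frames"` instead counts active frames rather than onsets — an
#' occupancy-style alternative, not equivalent to event counting for
#' multi-frame transients.
#'
#' @param b a `binary_raster`.
#' @param frame_interval_s seconds per frame; defaults to the raster's own.
#' @param cells optional cell selector: character ids or logical/integer index
#'   into the raster rows. Default: all cells.
#' @param mode `"onsets"` (default) or `"frames"`.
#' @return Mean events per minute over the selected cells (scalar).
#' @export
events_per_min <- function(b, frame_interval_s = b$frame_interval_s,
                           cells = NULL, mode = c("onsets", "frames")) {
  stopifnot(inherits(b, "binary_raster"))
  mode <- match.arg(mode)
  x <- b$values
  if (ncol(x) < 2L) stop("need at least two time points", call. = FALSE)
  idx <- if (is.null(cells)) seq_len(nrow(x))
  else if (is.character(cells)) match(trimws(cells), b$cell_ids)
  else which(rep_len(TRUE, nrow(x)))[cells]
  if (length(idx) == 0L || anyNA(idx))
    stop("empty or unknown cell selection for events_per_min", call. = FALSE)
  x <- x[idx, , drop = FALSE]
  counts <- if (mode == "onsets") {
    rowSums(x[, -1L, drop = FALSE] == 1L & x[, -ncol(x), drop = FALSE] == 0L) +
      (x[, 1L] == 1L)
  } else {
    rowSums(x)
  }
  minutes <- ncol(x) * frame_interval_s / 60
  mean(counts / minutes)
}

#' Hierarchical clustering of cells by activity pattern
#'
#' Agglomerative clustering of cells on their (normalized) trace row vectors,
#' primarily to order raster-plot rows so that co-active cells sit together.
#' The default is Ward's minimum-variance criterion in its squared-update
#' (Ward-2) formulation on Euclidean distances, which favors compact,
#' homogeneous groups; `complete`, `average` and `single` linkage probe other
#' structural assumptions.
#'
#' @param n a `normalized_traces` (or trace-shaped container).
#' @param linkage one of `"ward"`, `"complete"`, `"average"`, `"single"`.
#' @param metric distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @return A `cluster_order`: `ordering` (dendrogram leaf order, a permutation
#'   of cell indices), `linkage_method`, `merge_tree` (merge pairs and
#'   heights) and the underlying `hclust` object.
#' @export
cluster_traces <- function(n, linkage = c("ward", "complete", "average", "single"),
                           metric = "euclidean") {
  linkage <- match.arg(linkage)
  x <- trace_values(n)
  if (nrow(x) < 2L) stop("clustering requires at least two cells", call. = FALSE)
  d <- stats::dist(x, method = metric)
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
  structure(list(ordering = hc$order,
                 linkage_method = linkage,
                 merge_tree = data.frame(a = hc$merge[, 1L], b = hc$merge[, 2L],
                                         height = hc$height),
                 hclust = hc),
            class = "cluster_order")
}

#' Cut a cluster tree into k groups
#'
#' Convenience wrapper over [stats::cutree()] for a [cluster_traces()] result.
#'
#' @param co a `cluster_order`.
#' @param k number of groups.
#' @return Integer group membership per cell, in input cell order.
#' @export
cut_clusters <- function(co, k) {
  stopifnot(inherits(co, "cluster_order"))
  stats::cutree(co$hclust, k = k)
}
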