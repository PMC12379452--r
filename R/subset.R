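#' Induced subgraph of a labeled cell subset
#'
#' Restricts the functional graph to the cells carrying the given label,
#' keeping the same threshold and edge weights, so the subset's internal
#' network can be characterized with the same metrics as the full network.
#'
#' @param g a `functional_graph` whose nodes carry a `label` attribute.
#' @param label the label value selecting the subset.
#' @return A `functional_graph` on the labeled cells only.
#' @export
subset_graph <- function(g, label) {
  labs <- node_labels(g)
  sel <- which(labs == label)
  if (length(sel) == 0L)
    stop("label '", label, "' not present; available labels: ",
         paste(sort(unique(labs[nzchar(labs)])), collapse = ", "), call. = FALSE)
  structure(list(graph = igraph::induced_subgraph(g$graph, sel),
                 theta = g$theta),
            class = "functional_graph")
}

#' Labeled-to-unlabeled connection proportion (LtU)
#'
#' The number of graph edges joining a labeled cell to an unlabeled cell,
#' divided by the total number of possible labeled-unlabeled pairs
#' (`n_labeled * n_unlabeled`). It measures how integrated the labeled
#' subset is with the surrounding network: 0 means no cross connections,
#' 1 means every possible cross pair is connected.
#'
#' @param g a `functional_graph` with node labels.
#' @param label the label defining the subset; every other cell (including
#'   cells with a different label) counts as unlabeled.
#' @return Scalar in `[0, 1]`.
#' @export
ltu_proportion <- function(g, label) {
  labs <- node_labels(g)
  is_lab <- labs == label
  n_lab <- sum(is_lab); n_unl <- sum(!is_lab)
  if (n_lab == 0L)
    stop("label '", label, "' not present; available labels: ",
         paste(sort(unique(labs[nzchar(labs)])), collapse = ", "), call. = FALSE)
  if (n_unl == 0L)
    stop("every cell carries label '", label,
         "'; labeled-to-unlabeled proportion is undefined", call. = FALSE)
  ends <- igraph::as_edgelist(g$graph, names = FALSE)
  cross <- sum(is_lab[ends[, 1L]] != is_lab[ends[, 2L]])
  cross / (n_lab * n_unl)
}

#' Summary report for a labeled subset
#'
#' Bundles the three subset views: the induced subset network and its
#' topological metrics, the labeled-to-unlabeled connection proportion, and
#' the mean event frequency of the labeled cells.
#'
#' @param g a `functional_graph` with node labels.
#' @param b the `binary_raster` the graph was derived from.
#' @param label the subset label.
#' @param frame_interval_s seconds per frame (default: the raster's own).
#' @return A `subset_report`: `subset_ids`, `ltu`, `freq_labeled`
#'   (events/min) and `subset_metrics` (degrees, mean degree, clustering
#'   coefficient, and global efficiency — `NA` for a singleton subset).
#' @export
subset_summary <- function(g, b, label, frame_interval_s = b$frame_interval_s) {
  stopifnot(inherits(b, "binary_raster"))
  sg <- subset_graph(g, label)
  ids <- igraph::V(sg$graph)$name
  ds <- degree_stats(sg)
  metrics <- list(
    degrees = ds$degrees,
    mean_degree = ds$mean_degree,
    clustering_coeff = clustering_coefficient(sg),
    global_efficiency = if (igraph::vcount(sg$graph) >= 2L)
      global_efficiency(sg) else NA_real_)
  structure(list(subset_ids = ids,
                 ltu = ltu_proportion(g, label),
                 freq_labeled = events_per_min(b, frame_interval_s, cells = ids),
                 subset_metrics = metrics,
                 label = label),
            class = "subset_report")
}

#' @export
print.subset_report <- function(x, ...) {
  cat("<subset_report> label '", x$label, "': ", length(x$subset_ids),
      " cells, LtU = ", signif(x$ltu, 4), ", freq = ",
      signif(x$freq_labeled, 4), " events/min\n", sep = "")
  invisible(x)
}

# internal: per-node label vector, "" when absent
node_labels <- function(g) {
  stopifnot(inherits(g, "functional_graph"))
  labs <- igraph::V(g$graph)$label
  if (is.null(labs))
    stop("graph has no node labels; pass a cell table with a Label column to build_graph()",
         call. = FALSE)
  labs[is.na(labs)] <- ""
  labs
}
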