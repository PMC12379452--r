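#' Build the thresholded functional graph
#'
#' An undirected weighted graph over cells is built from the connectivity
#' matrix: an edge joins cells `i` and `j` whenever `rho_max[i, j] >= theta`
#' (inclusive), with the correlation retained as the edge weight. Setting
#' `theta = "none"` disables filtering (every pair with a nonzero
#' correlation is connected). Isolated nodes are retained, and cell
#' coordinates/labels travel with the nodes for plotting and subset analysis.
#'
#' All topological metrics downstream treat this graph as an unweighted
#' topology; weights are kept for display and export.
#'
#' @param c a [connectivity_matrix()].
#' @param theta edge threshold in `[0, 1]`, or the string `"none"` (`NULL` is
#'   accepted as a synonym). Default 0.3.
#' @param cells optional [cell_table()]; aligned to the connectivity matrix
#'   ids and stored as node attributes `x`, `y`, `label`.
#' @return A `functional_graph`: an igraph object plus the threshold used.
#' @export
build_graph <- function(c, theta = 0.3, cells = NULL) {
  stopifnot(inherits(c, "connectivity_matrix"))
  none <- is.null(theta) || (is.character(theta) && identical(tolower(theta), "none"))
  if (!none && (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 1))
    stop("theta must be a number in [0, 1] or \"none\"", call. = FALSE)
  R <- c$rho_max
  keep <- if (none) R > 0 else R >= theta
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  gr <- igraph::make_empty_graph(n = length(c$cell_ids), directed = FALSE)
  gr <- igraph::set_vertex_attr(gr, "name", value = c$cell_ids)
  if (nrow(idx) > 0L)
    gr <- igraph::add_edges(gr, t(idx), weight = R[idx])
  if (!is.null(cells)) {
    cells <- align_cells(c, cells)
    gr <- igraph::set_vertex_attr(gr, "x", value = cells$x)
    gr <- igraph::set_vertex_attr(gr, "y", value = cells$y)
    gr <- igraph::set_vertex_attr(gr, "label",
                                  value = ifelse(is.na(cells$label), "", cells$label))
  }
  theta_val <- if (none) NA_real_ else as.numeric(theta)
  gr <- igraph::set_graph_attr(gr, "theta", theta_val)
  structure(list(graph = gr, theta = theta_val), class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat("<functional_graph> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges, theta = ",
      ifelse(is.na(x$theta), "none", x$theta), "\n", sep = "")
  invisible(x)
}

# internal: dense 0/1 adjacency of the thresholded topology
graph_adjacency <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g$graph, type = "both", sparse = TRUE))
  A[A > 0] <- 1
  diag(A) <- 0
  A
}

#' Node degrees and mean degree
#'
#' The degree of a node is the number of edges incident to it; the mean
#' degree is `2|E| / N`.
#'
#' @param g a `functional_graph`.
#' @return List with `degrees` (named integer vector) and `mean_degree`.
#' @export
degree_stats <- function(g) {
  stopifnot(inherits(g, "functional_graph"))
  k <- igraph::degree(g$graph)
  list(degrees = k, mean_degree = mean(k))
}

#' Average clustering coefficient
#'
#' For each node with degree `k_i >= 2`, the local clustering coefficient is
#' `2 e_i / (k_i (k_i - 1))`, where `e_i` counts edges among the node's
#' neighbors; the network value is the average of these local coefficients.
#' Nodes of degree 0 or 1 have no neighbor pair and are excluded from the
#' average (set `count_low_degree = TRUE` to count them as zero instead);
#' when no node has degree 2 or more the coefficient is 0. Computed on the
#' unweighted thresholded topology.
#'
#' @param g a `functional_graph`.
#' @param count_low_degree include degree-<2 nodes as zeros in the average.
#' @return Scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(g, count_low_degree = FALSE) {
  stopifnot(inherits(g, "functional_graph"))
  A <- graph_adjacency(g)
  k <- rowSums(A)
  eligible <- k >= 2
  if (!any(eligible)) return(0)
  tri <- diag(A %*% A %*% A) / 2 # e_i: edges among neighbors of i
  local <- 2 * tri[eligible] / (k[eligible] * (k[eligible] - 1))
  if (count_low_degree) sum(local) / nrow(A) else mean(local)
}

#' Global efficiency
#'
#' The mean inverse shortest-path length over all ordered node pairs:
#' `G = (1 / (N (N - 1))) * sum_{i != j} 1 / d_ij`, with `d_ij` the
#' unweighted hop count and unreachable pairs contributing zero. High values
#' indicate short communication routes across the whole network; heavily
#' fragmented networks score near zero because most pairs are unreachable.
#'
#' @param g a `functional_graph` with at least two nodes.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "functional_graph"))
  n <- igraph::vcount(g$graph)
  if (n < 2L) stop("global efficiency requires at least two nodes", call. = FALSE)
  d <- igraph::distances(g$graph, weights = NA)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0 # unreachable pairs and the diagonal
  sum(inv) / (n * (n - 1))
}
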