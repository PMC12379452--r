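#' Leading-eigenvector community detection
#'
#' Newman's spectral method: the modularity matrix
#' `B_ij = A_ij - k_i k_j / (2m)` is bisected along the sign pattern of its
#' leading eigenvector, and the bisection is applied recursively to each part
#' using the generalized modularity matrix
#' `B^(g)_ij = B_ij - delta_ij * sum_{l in g} B_il`, stopping when the
#' leading eigenvalue is non-positive or the split no longer increases
#' modularity. Everything runs on the unweighted thresholded topology.
#'
#' The procedure is fully deterministic: the eigendecomposition is a dense
#' symmetric solve, the eigenvector sign is fixed so that its first
#' nonzero component is positive, zero components are grouped with the
#' negative side, and community indices are renumbered by first node
#' occurrence. An edgeless graph yields one singleton community per node with
#' modularity 0.
#'
#' @param g a `functional_graph`.
#' @param large_threshold a community is counted as "large" when it has
#'   strictly more members than this (default 5).
#' @return A `community_partition`: `membership` (named integer vector, one
#'   community index per node), `modularity` (direct evaluation of
#'   `Q = sum_c (e_c/m - (d_c/(2m))^2)` on the returned partition),
#'   `n_communities`, `large_community_count` and `sizes`.
#' @export
detect_communities <- function(g, large_threshold = 5) {
  stopifnot(inherits(g, "functional_graph"))
  A <- graph_adjacency(g)
  n <- nrow(A)
  m <- sum(A) / 2
  ids <- igraph::V(g$graph)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (m == 0) {
    membership <- stats::setNames(seq_len(n), ids)
    return(new_partition(membership, 0, large_threshold))
  }
  k <- rowSums(A)
  B <- A - outer(k, k) / (2 * m)
  membership <- integer(n)
  next_id <- 1L
  queue <- list(seq_len(n))
  while (length(queue)) {
    grp <- queue[[1L]]; queue <- queue[-1L]
    split <- split_group(B, grp, m)
    if (is.null(split)) {
      membership[grp] <- next_id
      next_id <- next_id + 1L
    } else {
      queue <- c(queue, list(split$left, split$right))
    }
  }
  # renumber by first occurrence for a canonical labeling
  membership <- match(membership, unique(membership))
  membership <- stats::setNames(membership, ids)
  new_partition(membership, modularity_value(A, membership), large_threshold)
}

# internal: attempt one spectral bisection of `grp`; NULL when indivisible
split_group <- function(B, grp, m, eig_tol = 1e-10, gain_tol = 1e-12) {
  if (length(grp) < 2L) return(NULL)
  Bg <- B[grp, grp, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg) # generalized modularity matrix
  es <- eigen(Bg, symmetric = TRUE)
  lead <- es$values[1L]
  if (lead <= eig_tol) return(NULL)
  v <- es$vectors[, 1L]
  nz <- which(abs(v) > 1e-12)
  if (length(nz) && v[nz[1L]] < 0) v <- -v # deterministic sign convention
  s <- ifelse(v > 0, 1, -1)
  if (all(s == s[1L])) return(NULL)
  gain <- as.numeric(t(s) %*% Bg %*% s) / (4 * m)
  if (gain <= gain_tol) return(NULL)
  list(left = grp[s > 0], right = grp[s < 0])
}

# internal: direct modularity Q = sum_c (e_c/m - (d_c/(2m))^2)
modularity_value <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (com in unique(membership)) {
    in_c <- membership == com
    e_c <- sum(A[in_c, in_c]) / 2
    d_c <- sum(k[in_c])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

new_partition <- function(membership, modularity, large_threshold) {
  sizes <- as.integer(table(membership))
  structure(list(membership = membership,
                 modularity = modularity,
                 n_communities = length(sizes),
                 large_community_count = sum(sizes > large_threshold),
                 sizes = sizes,
                 large_threshold = large_threshold),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition> ", x$n_communities, " communities (",
      x$large_community_count, " with > ", x$large_threshold,
      " members), Q = ", signif(x$modularity, 4), "\n", sep = "")
  invisible(x)
}

#' Attach a community assignment to a graph's nodes
#'
#' Stores the membership as node attribute `community` (used by graph export
#' and the network plot).
#'
#' @param g a `functional_graph`.
#' @param p a [detect_communities()] result.
#' @return The updated `functional_graph`.
#' @export
assign_communities <- function(g, p) {
  stopifnot(inherits(g, "functional_graph"), inherits(p, "community_partition"))
  g$graph <- igraph::set_vertex_attr(g$graph, "community",
                                     value = as.integer(p$membership))
  g
}
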