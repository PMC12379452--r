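# Independent brute-force oracles. Deliberately written as plain loops over
# the defining formulas so they share no code path with the implementation.

# cross-correlation: K(tau)/(sd_x sd_y), truncated sums, 1/T normalization
brute_ccf <- function(x, y, lag_max) {
  T <- length(x)
  mx <- sum(x) / T; my <- sum(y) / T
  sx <- sqrt(sum((x - mx)^2) / T)
  sy <- sqrt(sum((y - my)^2) / T)
  sapply(-lag_max:lag_max, function(tau) {
    acc <- 0
    for (t in 1:T) {
      tt <- t + tau
      if (tt >= 1 && tt <= T) acc <- acc + (x[tt] - mx) * (y[t] - my)
    }
    (acc / T) / (sx * sy)
  })
}

brute_degrees <- function(A) {
  n <- nrow(A)
  k <- numeric(n)
  for (i in 1:n) for (j in 1:n) if (i != j && A[i, j] == 1) k[i] <- k[i] + 1
  k
}

# average clustering coefficient, degree-<2 nodes excluded from the mean
brute_clustering <- function(A) {
  n <- nrow(A)
  vals <- c()
  for (i in 1:n) {
    nb <- which(A[i, ] == 1)
    if (length(nb) < 2) next
    e <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && A[nb[a], nb[b]] == 1) e <- e + 1
    }
    vals <- c(vals, 2 * e / (length(nb) * (length(nb) - 1)))
  }
  if (length(vals) == 0) 0 else sum(vals) / length(vals)
}

# global efficiency via hand-coded Floyd-Warshall hop counts
brute_efficiency <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A == 1] <- 1
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  acc <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i != j && is.finite(d[i, j])) acc <- acc + 1 / d[i, j]
  }
  acc / (n * (n - 1))
}

# direct modularity of a partition
brute_modularity <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A))) {
    if (membership[i] == membership[j])
      q <- q + (A[i, j] - k[i] * k[j] / (2 * m)) / (2 * m)
  }
  q
}

# all set partitions of 1..n (restricted-growth strings), for exhaustive
# modularity optimization on tiny graphs
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_max) {
    if (length(assign) == n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible(NULL))
    }
    for (g in 1:next_max) rec(c(assign, g), max(next_max, g + 1))
  }
  rec(integer(0), 1)
  out
}

best_partition_modularity <- function(A) {
  best <- -Inf
  for (p in all_partitions(nrow(A))) {
    q <- brute_modularity(A, p)
    if (q > best) best <- q
  }
  best
}

# ---- fixture builders ------------------------------------------------------

# functional_graph straight from a 0/1 adjacency matrix (weights = 1)
fg_from_adj <- function(A, labels = NULL, coords = NULL) {
  gr <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            diag = FALSE)
  n <- nrow(A)
  ids <- if (!is.null(rownames(A))) rownames(A) else paste0("c", seq_len(n))
  gr <- igraph::set_vertex_attr(gr, "name", value = ids)
  igraph::E(gr)$weight <- rep(1, igraph::ecount(gr))
  if (!is.null(labels))
    gr <- igraph::set_vertex_attr(gr, "label", value = labels)
  if (!is.null(coords)) {
    gr <- igraph::set_vertex_attr(gr, "x", value = coords[, 1])
    gr <- igraph::set_vertex_attr(gr, "y", value = coords[, 2])
  }
  structure(list(graph = gr, theta = NA_real_), class = "functional_graph")
}

random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < p)
  A + t(A)
}

adjacency_from_bits <- function(n, bits) {
  A <- matrix(0L, n, n)
  A[upper.tri(A)] <- bits
  A + t(A)
}

make_tm <- function(values, frame_interval_s = 1, ids = NULL) {
  trace_matrix(as.matrix(values), ids, frame_interval_s)
}

# two K3 cliques joined by one bridge edge (nodes 1:3 and 4:6, bridge 3-4)
two_triangle_bridge <- function() {
  A <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  A
}

# adjusted Rand index between two labelings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
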