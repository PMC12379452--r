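# connectivity_matrix stub with prescribed off-diagonal weights
cm_of <- function(R) {
  diag(R) <- 1
  ids <- paste0("c", seq_len(nrow(R)))
  dimnames(R) <- list(ids, ids)
  structure(list(rho_max = R, best_lag = matrix(0L, nrow(R), ncol(R)),
                 lag_set = -1:1, source = "binarized", cell_ids = ids),
            class = "connectivity_matrix")
}

test_that("edge thresholding is inclusive and 'none' disables filtering", {
  R <- matrix(0, 3, 3)
  R[1, 2] <- R[2, 1] <- 0.7
  R[1, 3] <- R[3, 1] <- 0.5
  R[2, 3] <- R[3, 2] <- 0.2
  g <- build_graph(cm_of(R), theta = 0.6)
  expect_equal(igraph::ecount(g$graph), 1)
  expect_equal(igraph::E(g$graph)$weight, 0.7)

  # inclusive >=: an exact tie at theta survives
  g_eq <- build_graph(cm_of(R), theta = 0.5)
  expect_equal(igraph::ecount(g_eq$graph), 2)

  # theta = 1.0 keeps only a perfectly correlated pair
  R2 <- R; R2[1, 2] <- R2[2, 1] <- 1
  g1 <- build_graph(cm_of(R2), theta = 1.0)
  expect_equal(igraph::ecount(g1$graph), 1)

  # "none": complete weighted graph on the non-degenerate pairs
  gn <- build_graph(cm_of(R), theta = "none")
  expect_equal(igraph::ecount(gn$graph), 3)
  R3 <- R; R3[2, 3] <- R3[3, 2] <- 0 # degenerate pair stays unconnected
  expect_equal(igraph::ecount(build_graph(cm_of(R3), theta = "none")$graph), 2)

  # isolated nodes are retained in V
  expect_equal(igraph::vcount(g$graph), 3)
  expect_error(build_graph(cm_of(R), theta = 1.5), "\\[0, 1\\]")
})

test_that("raising theta never adds edges and degrees are non-increasing", {
  set.seed(11)
  sim <- generate_population(synth_spec(n_cells = 15, n_time = 100, seed = 11))
  cm <- connectivity_matrix(binarize(normalize_minmax(sim$traces)))
  prev <- Inf
  prev_deg <- NULL
  for (th in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    g <- build_graph(cm, th)
    ec <- igraph::ecount(g$graph)
    expect_lte(ec, prev)
    deg <- degree_stats(g)$degrees
    if (!is.null(prev_deg)) expect_true(all(deg <= prev_deg))
    prev <- ec; prev_deg <- deg
  }
})

test_that("closed-form graphs give the textbook metric values", {
  K4 <- matrix(1L, 4, 4); diag(K4) <- 0L
  g4 <- fg_from_adj(K4)
  expect_equal(clustering_coefficient(g4), 1)
  expect_equal(global_efficiency(g4), 1)
  expect_equal(degree_stats(g4)$degrees, rep(3, 4), ignore_attr = TRUE)
  expect_equal(degree_stats(g4)$mean_degree, 3)

  # complete graphs of several orders are fully efficient
  for (n in c(2, 3, 6)) {
    Kn <- matrix(1L, n, n); diag(Kn) <- 0L
    expect_equal(global_efficiency(fg_from_adj(Kn)), 1)
  }

  # path on three nodes: no triangles, efficiency 5/6
  P3 <- matrix(0L, 3, 3); P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1L
  expect_equal(clustering_coefficient(fg_from_adj(P3)), 0)
  expect_equal(global_efficiency(fg_from_adj(P3)), 5 / 6)

  # triangle with a pendant node: local coefficients (1/3, 1, 1), pendant excluded
  TP <- matrix(0L, 4, 4)
  TP[1, 2] <- TP[2, 1] <- TP[1, 3] <- TP[3, 1] <- TP[2, 3] <- TP[3, 2] <- 1L
  TP[1, 4] <- TP[4, 1] <- 1L
  expect_equal(clustering_coefficient(fg_from_adj(TP)), 7 / 9)
  # counting the degree-1 pendant as zero changes the average
  expect_equal(clustering_coefficient(fg_from_adj(TP), count_low_degree = TRUE),
               (1 / 3 + 1 + 1) / 4)

  # two disjoint edges: unreachable pairs contribute zero
  D <- matrix(0L, 4, 4); D[1, 2] <- D[2, 1] <- D[3, 4] <- D[4, 3] <- 1L
  expect_equal(global_efficiency(fg_from_adj(D)), 1 / 3)

  # degenerate cases
  E4 <- fg_from_adj(matrix(0L, 4, 4))
  expect_equal(clustering_coefficient(E4), 0)
  expect_equal(global_efficiency(E4), 0)
  expect_equal(degree_stats(E4)$degrees, rep(0, 4), ignore_attr = TRUE)
  expect_error(global_efficiency(fg_from_adj(matrix(0L, 1, 1))), "two nodes")
})

test_that("metrics agree with brute force on exhaustive small graphs", {
  # every labeled graph on 4 nodes
  for (bits in 0:(2^6 - 1)) {
    A <- adjacency_from_bits(4, as.integer(intToBits(bits))[1:6])
    g <- fg_from_adj(A)
    expect_equal(clustering_coefficient(g), brute_clustering(A))
    expect_equal(global_efficiency(g), brute_efficiency(A))
    expect_equal(unname(degree_stats(g)$degrees), brute_degrees(A))
  }
  # random graphs on 5-8 nodes, mixed densities
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(5:8, 1)
    A <- random_adjacency(n, runif(1, 0.15, 0.8))
    g <- fg_from_adj(A)
    expect_equal(clustering_coefficient(g), brute_clustering(A), tolerance = 1e-12)
    expect_equal(global_efficiency(g), brute_efficiency(A), tolerance = 1e-12)
    expect_equal(unname(degree_stats(g)$degrees), brute_degrees(A))
  }
})

test_that("degree stats equal the handshake count from the edge list", {
  set.seed(9)
  A <- random_adjacency(8, 0.4)
  g <- fg_from_adj(A)
  ds <- degree_stats(g)
  el <- igraph::as_edgelist(g$graph, names = TRUE)
  hand <- table(factor(c(el[, 1], el[, 2]), levels = igraph::V(g$graph)$name))
  expect_equal(unname(ds$degrees), as.integer(hand))
  expect_equal(ds$mean_degree, 2 * nrow(el) / 8)
})
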