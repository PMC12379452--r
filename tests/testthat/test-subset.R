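# labeled 5-node fixture: cells 1-2 labeled, edges 1-3, 2-4 cross + 1-2 internal
labeled_fixture <- function() {
  A <- matrix(0L, 5, 5)
  A[1, 2] <- A[2, 1] <- 1L
  A[1, 3] <- A[3, 1] <- 1L
  A[2, 4] <- A[4, 2] <- 1L
  fg_from_adj(A, labels = c("RFP", "RFP", "none", "none", "none"),
              coords = cbind(1:5, 1:5))
}

test_that("subset graph is the induced subgraph on the labeled cells", {
  g <- labeled_fixture()
  sg <- subset_graph(g, "RFP")
  expect_equal(igraph::vcount(sg$graph), 2)
  expect_equal(igraph::ecount(sg$graph), 1)

  # labeled singleton
  A <- matrix(0L, 3, 3)
  g1 <- fg_from_adj(A, labels = c("RFP", "none", "none"))
  sg1 <- subset_graph(g1, "RFP")
  expect_equal(igraph::vcount(sg1$graph), 1)
  expect_equal(igraph::ecount(sg1$graph), 0)

  # label covering every cell reproduces the graph
  g_all <- fg_from_adj(two_triangle_bridge(), labels = rep("RFP", 6))
  sg_all <- subset_graph(g_all, "RFP")
  expect_equal(igraph::ecount(sg_all$graph), 7)

  expect_error(subset_graph(g, "GFP"), "available labels: .*RFP")
})

test_that("LtU is cross edges over all possible cross pairs", {
  expect_equal(ltu_proportion(labeled_fixture(), "RFP"), 2 / 6)

  # no cross edges
  A <- matrix(0L, 4, 4); A[1, 2] <- A[2, 1] <- 1L
  g0 <- fg_from_adj(A, labels = c("RFP", "RFP", "none", "none"))
  expect_equal(ltu_proportion(g0, "RFP"), 0)

  # complete bipartite cross-connectivity attains 1
  A <- matrix(0L, 5, 5)
  for (i in 1:2) for (j in 3:5) A[i, j] <- A[j, i] <- 1L
  g1 <- fg_from_adj(A, labels = c("RFP", "RFP", "none", "none", "none"))
  expect_equal(ltu_proportion(g1, "RFP"), 1)

  expect_error(ltu_proportion(g1, "GFP"), "available labels")
  g_all <- fg_from_adj(matrix(0L, 3, 3), labels = rep("RFP", 3))
  expect_error(ltu_proportion(g_all, "RFP"), "undefined")
})

test_that("edges partition into labeled-internal, unlabeled-internal and cross", {
  set.seed(13)
  for (rep in 1:100) {
    n <- sample(5:12, 1)
    A <- random_adjacency(n, runif(1, 0.2, 0.7))
    n_lab <- sample(1:(n - 1), 1)
    labs <- c(rep("RFP", n_lab), rep("none", n - n_lab))[sample(n)]
    g <- fg_from_adj(A, labels = labs)
    is_lab <- labs == "RFP"
    e_lab <- sum(A[is_lab, is_lab]) / 2
    e_unl <- sum(A[!is_lab, !is_lab]) / 2
    cross <- ltu_proportion(g, "RFP") * sum(is_lab) * sum(!is_lab)
    expect_equal(e_lab + e_unl + cross, sum(A) / 2)
    # formula symmetry: swapping the roles of the two groups leaves LtU fixed
    swapped <- ifelse(labs == "RFP", "none", "RFP")
    g_sw <- fg_from_adj(A, labels = swapped)
    expect_equal(ltu_proportion(g_sw, "RFP"), ltu_proportion(g, "RFP"))
  }
})

test_that("subset summary composes its three components", {
  sim <- generate_population(synth_spec(n_cells = 10, n_time = 120,
                                        labeled_fraction = 0.3, seed = 21))
  nz <- normalize_minmax(sim$traces)
  b <- binarize(nz)
  g <- build_graph(connectivity_matrix(b), 0.3, sim$cells)
  rep <- subset_summary(g, b, "RFP")
  expect_equal(rep$ltu, ltu_proportion(g, "RFP"))
  expect_equal(rep$freq_labeled, events_per_min(b, cells = rep$subset_ids))
  sg <- subset_graph(g, "RFP")
  expect_equal(rep$subset_metrics$mean_degree, degree_stats(sg)$mean_degree)
  expect_equal(rep$subset_metrics$clustering_coeff, clustering_coefficient(sg))
  expect_setequal(rep$subset_ids, sim$cells$cell[sim$cells$label == "RFP"])
})

test_that("silent labeled cells report zero event frequency", {
  x <- rbind(a = c(0, 0, 0, 0), b = c(0, 1, 0, 1), c = c(1, 0, 1, 0))
  b <- binarize(make_tm(x, 15, ids = rownames(x)),
                custom_rule = function(v) v > 0.5)
  A <- matrix(0L, 3, 3); A[2, 3] <- A[3, 2] <- 1L
  dimnames(A) <- list(rownames(x), rownames(x))
  g <- fg_from_adj(A, labels = c("RFP", "none", "none"))
  rep <- subset_summary(g, b, "RFP")
  expect_equal(rep$freq_labeled, 0)
  expect_true(is.na(rep$subset_metrics$global_efficiency)) # singleton subset
})

test_that("weakening labeled-cell coupling lowers LtU against a matched control", {
  run_ltu <- function(labeled_coupling, seed) {
    sim <- generate_population(synth_spec(labeled_coupling = labeled_coupling,
                                          seed = seed))
    b <- binarize(normalize_minmax(sim$traces))
    g <- build_graph(connectivity_matrix(b), 0.3, sim$cells)
    ltu_proportion(g, "RFP")
  }
  wins <- sum(sapply(1:5, function(s) run_ltu(0.3, s) < run_ltu(1, s)))
  expect_gte(wins, 4)
})
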