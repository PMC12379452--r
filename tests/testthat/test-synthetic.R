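test_that("generation is bitwise reproducible and leaves the caller's RNG alone", {
  spec <- synth_spec(n_cells = 20, n_time = 100, seed = 5)
  a <- generate_population(spec)
  set.seed(123)
  before <- .Random.seed
  b <- generate_population(spec)
  expect_identical(.Random.seed, before)
  expect_identical(a$traces$values, b$traces$values)
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth$assembly_of, b$truth$assembly_of)

  c <- generate_population(synth_spec(n_cells = 20, n_time = 100, seed = 6))
  expect_false(identical(a$traces$values, c$traces$values))
})

test_that("invalid spec fields are rejected by name", {
  expect_error(synth_spec(n_assemblies = 99, n_cells = 10), "n_assemblies")
  expect_error(synth_spec(within_coupling = 1.2), "within_coupling")
  expect_error(synth_spec(event_rate_hz = 1, frame_interval_s = 2),
               "event_rate_hz")
  expect_error(synth_spec(amplitude_range = c(2, 1)), "amplitude_range")
  expect_error(synth_spec(labeled_rate_multiplier = 0),
               "labeled_rate_multiplier")
  expect_error(synth_spec(noise_sd = -1), "noise_sd")
})

test_that("ground truth is consistent with the emitted tables", {
  sim <- generate_population(synth_spec(n_cells = 30, n_time = 60, seed = 9,
                                        labeled_fraction = 0.2))
  expect_equal(sim$cells$cell, sim$traces$cell_ids)
  expect_equal(sum(sim$truth$labeled), round(0.2 * 30))
  expect_equal(sim$cells$label == "RFP", unname(sim$truth$labeled))
  expect_equal(dim(sim$truth$true_pair_coupled), c(30, 30))
  expect_true(all(diag(sim$truth$true_pair_coupled) == FALSE))
  same <- outer(sim$truth$assembly_of, sim$truth$assembly_of, `==`)
  diag(same) <- FALSE
  expect_equal(unname(sim$truth$true_pair_coupled), unname(same))
})

test_that("noise-free fully-coupled assemblies are perfectly correlated at lag 0", {
  sim <- generate_population(synth_spec(n_cells = 12, n_time = 200, seed = 4,
                                        noise_sd = 0, within_coupling = 1,
                                        cross_coupling = 0,
                                        labeled_fraction = 0))
  nz <- normalize_minmax(sim$traces)
  cm <- connectivity_matrix(nz, lag_max = 1)
  same <- sim$truth$true_pair_coupled
  expect_equal(unname(cm$rho_max[same]), rep(1, sum(same)), tolerance = 1e-9)
  expect_true(all(cm$best_lag[same] == 0L))
})

test_that("connectivity is invariant to per-cell gain", {
  sim <- generate_population(synth_spec(n_cells = 8, n_time = 120, seed = 14))
  scaled <- sim$traces
  scaled$values[3, ] <- 50 * scaled$values[3, ]
  nz1 <- normalize_minmax(sim$traces); nz2 <- normalize_minmax(scaled)
  expect_equal(nz1$values, nz2$values, tolerance = 1e-12)
  b1 <- binarize(nz1); b2 <- binarize(nz2)
  expect_identical(b1$values, b2$values)
  expect_equal(connectivity_matrix(nz1)$rho_max,
               connectivity_matrix(nz2)$rho_max, tolerance = 1e-9)
})

test_that("a labeled rate multiplier above one raises the labeled event frequency", {
  diffs <- sapply(1:6, function(s) {
    sim <- generate_population(synth_spec(labeled_rate_multiplier = 1.8,
                                          seed = s))
    b <- binarize(normalize_minmax(sim$traces))
    lab <- sim$cells$cell[sim$cells$label == "RFP"]
    events_per_min(b, cells = lab) - events_per_min(b)
  })
  expect_gte(sum(diffs > 0), 5)
})

test_that("community recovery degrades, not improves, with added noise", {
  recover <- function(noise_sd, seed) {
    sim <- generate_population(synth_spec(noise_sd = noise_sd, seed = seed,
                                          labeled_fraction = 0))
    b <- binarize(normalize_minmax(sim$traces))
    g <- build_graph(connectivity_matrix(b), 0.3)
    ari(detect_communities(g)$membership, sim$truth$assembly_of)
  }
  seeds <- 1:5
  low <- median(sapply(seeds, function(s) recover(0.05, s)))
  high <- median(sapply(seeds, function(s) recover(1.5, s)))
  expect_gte(low, high)
  expect_gte(low, 0.9)
})
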