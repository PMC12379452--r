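# binary_raster straight from a 0/1 matrix
raster_of <- function(x, fi = 1) binarize(make_tm(x, fi), custom_rule = function(v) v > 0.5)

test_that("active percentage follows the column means of the raster", {
  b <- raster_of(rbind(c(1, 0, 1, 0), c(1, 1, 0, 0), c(1, 0, 0, 0), c(1, 0, 1, 0)))
  act <- active_percentage(b)
  expect_equal(act$percent_active, c(100, 25, 50, 0))
  expect_equal(act$time_s, 0:3)

  # two cells both active at one frame -> 100 there
  b2 <- raster_of(rbind(c(0, 1, 0), c(0, 1, 0)))
  expect_equal(active_percentage(b2)$percent_active[2], 100)

  # all-silent raster -> flat zero
  expect_equal(active_percentage(raster_of(matrix(0, 3, 5)))$percent_active,
               rep(0, 5))
})

test_that("active percentage conserves the total number of active samples", {
  set.seed(5)
  for (rep in 1:10) {
    x <- matrix(rbinom(6 * 25, 1, 0.3), 6)
    b <- raster_of(x)
    act <- active_percentage(b)
    expect_equal(sum(act$percent_active) * 6 / 100, sum(x))
  }
})

test_that("event frequency counts rising edges per minute", {
  # 2 onsets over 2.5 minutes
  b <- raster_of(rbind(c(0, 1, 1, 0, 1)), fi = 30)
  expect_equal(events_per_min(b), 0.8)

  expect_equal(events_per_min(raster_of(matrix(0, 2, 10), fi = 6)), 0)

  # always-active cell over one minute: the single onset at recording start
  b1 <- raster_of(matrix(1, 1, 60), fi = 1)
  expect_equal(events_per_min(b1), 1)

  # rate scales inversely with duration via the frame interval
  expect_equal(events_per_min(b, frame_interval_s = 60),
               events_per_min(b, frame_interval_s = 30) / 2)

  # frames mode counts occupancy instead of onsets
  expect_equal(events_per_min(b, mode = "frames"), 3 / 2.5)
})

test_that("event frequency restricts to a selected subset", {
  x <- rbind(a = c(0, 1, 0, 1), b = c(0, 0, 0, 0))
  b <- binarize(make_tm(x, 15, ids = c("a", "b")),
                custom_rule = function(v) v > 0.5)
  expect_equal(events_per_min(b, cells = "a"), 2)
  expect_equal(events_per_min(b, cells = "b"), 0)
  expect_equal(events_per_min(b), 1)
  expect_error(events_per_min(b, cells = character(0)), "empty or unknown")
  expect_error(events_per_min(b, cells = "zzz"), "empty or unknown")
})

test_that("hierarchical clustering recovers well-separated trace groups", {
  # two groups of near-identical traces, far apart: k = 2 cut is exact
  base1 <- sin(seq(0, 4 * pi, length.out = 40))
  base2 <- 10 + cos(seq(0, 4 * pi, length.out = 40))
  set.seed(1)
  x <- rbind(base1, base1 + 0.01, base1 - 0.01,
             base2, base2 + 0.01, base2 - 0.01)
  for (link in c("ward", "complete", "average", "single")) {
    co <- cluster_traces(make_tm(x), linkage = link)
    groups <- cut_clusters(co, 2)
    expect_equal(ari(groups, c(1, 1, 1, 2, 2, 2)), 1)
    expect_setequal(co$ordering, 1:6)
  }

  # two cells: one merge, ordering a permutation of both
  co2 <- cluster_traces(make_tm(rbind(c(1, 2, 3), c(3, 2, 1))))
  expect_setequal(co2$ordering, 1:2)
  expect_equal(nrow(co2$merge_tree), 1)

  # duplicate traces merge at height zero before anything else
  co3 <- cluster_traces(make_tm(rbind(c(1, 2), c(1, 2), c(9, 9))))
  expect_equal(co3$merge_tree$height[1], 0)
  expect_setequal(abs(unlist(co3$merge_tree[1, c("a", "b")])), c(1, 2))

  expect_error(cluster_traces(make_tm(rbind(c(1, 2, 3))), linkage = "median"),
               "'arg'")
  expect_error(cluster_traces(make_tm(rbind(c(1, 2, 3)))), "two cells")
})

test_that("ward merge heights are non-decreasing and ordering deterministic", {
  set.seed(23)
  x <- matrix(rnorm(10 * 30), 10)
  co <- cluster_traces(make_tm(x))
  expect_true(all(diff(co$merge_tree$height) >= -1e-12))
  expect_identical(co$ordering, cluster_traces(make_tm(x))$ordering)
})
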