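graph_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  }
  A
}

test_that("assortativity reproduces the analytic graph values", {
  path3 <- graph_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(assortativity(path3), -1)

  star4 <- graph_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(assortativity(star4), -1)

  tri_edge <- graph_from_edges(5, list(c(1, 2), c(1, 3), c(2, 3), c(4, 5)))
  expect_equal(assortativity(tri_edge), 1)

  cycle4 <- graph_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  expect_true(is.na(assortativity(cycle4))) # regular: zero degree variance
  expect_true(is.na(assortativity(matrix(0L, 4, 4)))) # empty graph
})

test_that("assortativity equals the end-degree Pearson correlation (oracle + igraph)", {
  skip_if_not_installed("igraph")
  set.seed(77)
  checked <- 0
  while (checked < 100) {
    n <- sample(4:20, 1)
    A <- random_adjacency(n, runif(1, 0.15, 0.7))
    a <- assortativity(A)
    o <- oracle_assortativity(A)
    if (is.na(a) || is.na(o)) {
      expect_identical(is.na(a), is.na(o))
      next
    }
    expect_equal(a, o, tolerance = 1e-10)
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(a, igraph::assortativity_degree(ig), tolerance = 1e-10)
    expect_true(a >= -1 - 1e-12 && a <= 1 + 1e-12)
    checked <- checked + 1
  }
})

test_that("clustering coefficients match hand counts and triangle oracle", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(local_clustering(tri), rep(1, 3))

  path3 <- graph_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(local_clustering(path3, 2), 0) # unconnected neighbours
  expect_equal(local_clustering(path3, 1), 0) # k = 1 convention

  k5 <- matrix(1, 5, 5) - diag(5)
  expect_equal(mean_clustering(k5), 1)
  star4 <- graph_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(mean_clustering(star4), 0)
  tri_iso <- graph_from_edges(4, list(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(mean_clustering(tri_iso), 0.75)

  set.seed(19)
  for (i in 1:30) {
    A <- random_adjacency(sample(4:15, 1), runif(1, 0.2, 0.8))
    cn <- local_clustering(A)
    expect_equal(mean_clustering(A), oracle_mean_clustering(A),
                 tolerance = 1e-12)
    expect_true(all(cn >= 0 & cn <= 1))
  }
})

test_that("ER ensembles are degree-degree uncorrelated up to finite size", {
  bl <- er_baseline(100, 0.1, 20, seed = 101)
  expect_lt(abs(bl$mean_a), 3 * bl$sd_a / sqrt(20) + 0.05)
  expect_gt(bl$sd_a, 0)

  expect_identical(unclass(er_baseline(50, 0.2, 20, seed = 5)),
                   unclass(er_baseline(50, 0.2, 20, seed = 5)))

  expect_warning(one <- er_baseline(30, 0.2, 1, seed = 3), "sd_a set to 0")
  expect_equal(one$sd_a, 0)

  # exact link count in every realization is implied by the construction;
  # check via a direct draw of the same generator settings
  expect_error(er_baseline(5, 0.01), "achievable")
})

test_that("genuineness flag fires strictly beyond one ensemble sd", {
  bl <- er_baseline(60, 0.1, 20, seed = 8)
  expect_false(is_genuine(bl$mean_a, bl))
  expect_true(is_genuine(bl$mean_a + 2 * bl$sd_a, bl))
  expect_false(is_genuine(bl$mean_a - bl$sd_a, bl)) # boundary: strict
  expect_true(is.na(is_genuine(NA_real_, bl)))
})

test_that("per-window metrics keep undefined assortativity flagged", {
  sim <- small_sim()
  tc <- sim$record |>
    bandpass_filter() |>
    sync_timecourse() |>
    threshold_networks(rho = 0.2) |>
    network_metrics()
  expect_true(all(c("a", "C", "a_defined") %in% names(tc)))
  expect_identical(tc$a_defined, !is.na(tc$a))
  expect_true(all(tc$C >= 0 & tc$C <= 1))
  defined <- tc$a[tc$a_defined]
  expect_true(all(defined >= -1 & defined <= 1))
})
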