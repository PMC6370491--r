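two_cliques <- function(k = 3L) {
  n <- 2L * k
  a <- matrix(0, n, n)
  a[1:k, 1:k] <- 1
  a[(k + 1):n, (k + 1):n] <- 1
  diag(a) <- 0
  a
}

test_that("Newman-Girvan null reproduces hand computations and conserves weight", {
  a2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(newman_girvan_null(a2), matrix(0.5, 2, 2))
  # ring of n nodes, unit weights: kappa = 2, 2m = 2n, P = 4 / (2n)
  n <- 7L
  ring <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    ring[i, j] <- ring[j, i] <- 1
  }
  p <- newman_girvan_null(ring)
  expect_true(all(abs(p - 2 / n) < 1e-12))
  expect_equal(sum(p), sum(ring), tolerance = 1e-12)
  expect_warning(p0 <- newman_girvan_null(matrix(0, 3, 3)), "zero total")
  expect_equal(p0, matrix(0, 3, 3))
})

test_that("quality reproduces closed-form values on canonical fixtures", {
  # single layer, one community: sum(A - P) = 0
  set.seed(3)
  a <- matrix(runif(25), 5, 5); a <- (a + t(a)) / 2; diag(a) <- 0
  net1 <- multilayer_network(list(a), omega = 0)
  expect_equal(modularity_quality(net1, matrix(1, 5, 1)), 0,
               tolerance = 1e-12)
  # two disconnected equal cliques at the clique partition
  netc <- multilayer_network(list(two_cliques(3L)), omega = 0)
  labc <- matrix(rep(1:2, each = 3), 6, 1)
  expect_equal(modularity_quality(netc, labc), 0.5, tolerance = 1e-12)
  # one node, two empty layers, identity coupling: Q = 2 omega / (2 mu) = 1
  z1 <- matrix(0, 1, 1)
  net2 <- suppressWarnings(multilayer_network(list(z1, z1), omega = 1))
  expect_equal(suppressWarnings(modularity_quality(net2, matrix(1, 1, 2))),
               1, tolerance = 1e-12)
})

test_that("quality is invariant under community relabeling", {
  set.seed(11)
  net <- rand_multilayer(5L, 2L)
  lab <- matrix(sample(1:3, net$n * net$n_layers, replace = TRUE),
                net$n, net$n_layers)
  perm <- sample(10)
  expect_equal(suppressWarnings(modularity_quality(net, lab)),
               suppressWarnings(modularity_quality(net, matrix(
                 perm[lab], net$n, net$n_layers))),
               tolerance = 1e-14)
})

test_that("quality is non-decreasing in omega for temporally consistent labels", {
  set.seed(13)
  a <- matrix(runif(36), 6, 6); a <- (a + t(a)) / 2; diag(a) <- 0
  lab <- matrix(rep(sample(1:2, 6, replace = TRUE), 3), 6, 3)
  qs <- vapply(c(0, 0.5, 1, 2, 5), function(om) {
    modularity_quality(multilayer_network(list(a, a, a), omega = om), lab)
  }, 0)
  expect_false(is.unsorted(qs))
})

test_that("brute force finds the known optima of canonical instances", {
  netc <- multilayer_network(list(two_cliques(3L)), omega = 0)
  bf <- brute_force_max(netc)
  expect_equal(bf$Q, 0.5, tolerance = 1e-12)
  expect_identical(bf$labels[, 1L], rep(1:2, each = 3L))
  # complete unit-weight graph: optimum is one community at Q = 0
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  bfc <- brute_force_max(multilayer_network(list(k4), omega = 0))
  expect_equal(bfc$Q, 0, tolerance = 1e-12)
  # empty layers with coupling: optimum is temporally persistent
  z2 <- matrix(0, 2, 2)
  bfe <- suppressWarnings(brute_force_max(
    multilayer_network(list(z2, z2), omega = 1)))
  expect_identical(bfe$labels[, 1L], bfe$labels[, 2L])
  expect_equal(bfe$Q, 1, tolerance = 1e-12)
  a13 <- matrix(1, 13, 13); diag(a13) <- 0
  big <- multilayer_network(list(a13), omega = 0)
  expect_error(brute_force_max(big), "limited")
})

test_that("generalized Louvain recovers planted multilayer structure deterministically", {
  a <- two_cliques(4L)
  net <- multilayer_network(list(a, a, a), omega = 1)
  mm <- maximize_modularity(net, n_iterations = 20L, seed = 5L)
  planted <- matrix(rep(rep(1:2, each = 4L), 3L), 8L, 3L)
  for (p in mm$partitions) {
    expect_identical(p$labels, planted)
  }
  expect_equal(mm$mean_Q, modularity_quality(net, planted),
               tolerance = 1e-12)
  # determinism and Q consistency
  mm2 <- maximize_modularity(net, n_iterations = 20L, seed = 5L)
  expect_identical(mm, mm2)
  for (p in mm$partitions) {
    expect_equal(p$Q, modularity_quality(net, p$labels), tolerance = 1e-14)
  }
})

test_that("Louvain attains the exhaustive optimum on random small instances", {
  set.seed(42)
  for (k in 1:8) {
    net <- rand_multilayer()
    mm <- maximize_modularity(net, n_iterations = 50L, seed = k)
    bf <- brute_force_max(net)
    expect_equal(max(mm$Q_values), bf$Q, tolerance = 1e-12)
  }
})

test_that("Louvain partitions are stable to any single-slot relabeling", {
  set.seed(77)
  net <- rand_multilayer(4L, 2L)
  mm <- maximize_modularity(net, n_iterations = 30L, seed = 3L)
  best <- mm$partitions[[mm$best]]
  q0 <- best$Q
  lab <- best$labels
  all_labs <- seq_len(max(lab) + 1L)
  for (i in seq_len(nrow(lab))) {
    for (l in seq_len(ncol(lab))) {
      for (g in setdiff(all_labs, lab[i, l])) {
        alt <- lab
        alt[i, l] <- g
        expect_lte(modularity_quality(net, alt), q0 + 1e-12)
      }
    }
  }
})

test_that("single-layer quality matches igraph's modularity", {
  set.seed(19)
  a <- matrix(runif(49), 7, 7); a <- (a + t(a)) / 2
  a[a < 0.5] <- 0; diag(a) <- 0
  lab <- sample(1:3, 7, replace = TRUE)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE)
  q_ig <- igraph::modularity(g, lab, weights = igraph::E(g)$weight)
  net <- multilayer_network(list(a), omega = 0)
  expect_equal(modularity_quality(net, matrix(lab, 7, 1)), q_ig,
               tolerance = 1e-12)
})
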