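test_that("closed-form graphs give textbook metric values", {
  K5 <- make_net(matrix(1L, 5, 5) - diag(1L, 5))
  expect_equal(net_clustering(K5)$mean, 1)
  expect_equal(characteristic_path_length(K5), 1)
  expect_equal(global_efficiency(K5), 1)

  # triangle
  K3 <- make_net(matrix(1L, 3, 3) - diag(1L, 3))
  expect_equal(net_clustering(K3)$per_node, rep(1, 3), ignore_attr = TRUE)

  # 4-path: no triangles
  A4 <- matrix(0L, 4, 4); A4[1, 2] <- A4[2, 3] <- A4[3, 4] <- 1L
  expect_equal(net_clustering(make_net(A4 + t(A4)))$mean, 0)

  # 5-cycle: distances 1,1,2,2 per node
  C5 <- make_net(ring_lattice(5, 2))
  expect_equal(characteristic_path_length(C5), 1.5)
  expect_equal(global_efficiency(C5), 0.75)

  # two disconnected K2: 6 ordered-pair distances, two finite
  A <- matrix(0L, 4, 4); A[1, 2] <- A[3, 4] <- 1L; A <- A + t(A)
  expect_equal(global_efficiency(make_net(A)), 1 / 3)
  expect_error(characteristic_path_length(make_net(A)), "disconnected")

  # star: center betweenness 1, leaves 0
  S <- matrix(0L, 6, 6); S[1, 2:6] <- 1L; S <- S + t(S)
  b <- net_betweenness(make_net(S))
  expect_equal(unname(b[1]), 1)
  expect_equal(unname(b[2:6]), rep(0, 5))

  # 5-path: middle node carries 4 of 6 shortest paths
  P5 <- matrix(0L, 5, 5)
  P5[cbind(1:4, 2:5)] <- 1L; P5 <- P5 + t(P5)
  expect_equal(unname(net_betweenness(make_net(P5))[3]), 4 / 6)
})

test_that("metrics agree with brute-force oracles on random graphs", {
  for (s in 1:12) {
    n <- sample(5:12, 1)
    A <- random_connected_graph(n, runif(1, 0.3, 0.7), seed = 100 + s)
    net <- make_net(A)
    expect_equal(net_clustering(net)$mean, bf_clustering(A)$mean,
                 tolerance = 1e-12)
    expect_equal(net_clustering(net)$per_node, bf_clustering(A)$per_node,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(characteristic_path_length(net), bf_path_length(A),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(net), bf_efficiency(A), tolerance = 1e-12)
    expect_equal(unname(net_betweenness(net)), bf_betweenness(A),
                 tolerance = 1e-10)
  }
})

test_that("degree sums equal twice the edge count", {
  for (s in 1:5) {
    A <- er_graph(30, 0.2, seed = 200 + s)
    expect_equal(sum(net_degree(make_net(A))), sum(A))
  }
})

test_that("rewiring preserves degrees, is seeded, and randomizes a lattice", {
  A <- ring_lattice(60, 6)
  net <- make_net(A)
  r1 <- rewire_degree_preserving(net, seed = 5)
  r2 <- rewire_degree_preserving(net, seed = 5)
  r3 <- rewire_degree_preserving(net, seed = 6)
  expect_identical(r1$adjacency, r2$adjacency)
  expect_false(identical(r1$adjacency, r3$adjacency))
  expect_equal(rowSums(r1$adjacency), rowSums(A), ignore_attr = TRUE)
  expect_equal(diag(r1$adjacency), rep(0L, 60), ignore_attr = TRUE)
  # rewiring destroys lattice clustering
  expect_lt(net_clustering(r1)$mean, net_clustering(net)$mean)
  # connected variant keeps the graph whole
  expect_true(igraph::is_connected(as_igraph(r1)))
})

test_that("small-world indices: lattice is small-world-like, rewired self is null", {
  lat <- make_net(ring_lattice(60, 6))
  sw <- normalized_small_world(lat, n_random = 8, seed = 9)
  expect_gt(sw$gamma, 1.5)
  # a rewired copy of a graph scores sigma ~ 1 against its own ensemble
  rnd <- rewire_degree_preserving(lat, seed = 10)
  sw2 <- normalized_small_world(rnd, n_random = 8, seed = 11)
  expect_lt(abs(sw2$sigma - 1), 0.15)
})

test_that("modularity: closed forms and planted partitions", {
  # two disconnected K5 cliques: Q = 0.5 exactly
  A <- matrix(0L, 10, 10)
  A[1:5, 1:5] <- 1L; A[6:10, 6:10] <- 1L; diag(A) <- 0L
  mod <- modularity_optimal(make_net(A), n_iter = 20, seed = 2)
  expect_equal(mod$Q, 0.5, tolerance = 1e-12)
  expect_equal(mod$n_modules, 2L)

  # complete graph: no structure, Q = 0, single module
  K8 <- make_net(matrix(1L, 8, 8) - diag(1L, 8))
  modK <- modularity_optimal(K8, n_iter = 10, seed = 3)
  expect_equal(modK$Q, 0)
  expect_gte(modK$Q, 0)   # never below the single-community baseline

  # planted 4-block graph recovered
  set.seed(4)
  blocks <- rep(1:4, each = 10)
  A4 <- matrix(0L, 40, 40)
  for (i in 1:39) for (j in (i + 1):40) {
    p <- if (blocks[i] == blocks[j]) 0.9 else 0.05
    A4[i, j] <- A4[j, i] <- rbinom(1, 1, p)
  }
  mod4 <- modularity_optimal(make_net(A4), n_iter = 50, seed = 5)
  agree <- mean(outer(mod4$partition, mod4$partition, "==") ==
                outer(blocks, blocks, "=="))
  expect_gt(agree, 0.9)
  expect_equal(mod4$n_modules, 4L)
})

test_that("restarted greedy modularity matches exhaustive search on small graphs", {
  for (s in 1:6) {
    A <- random_connected_graph(6, 0.45, seed = 300 + s)
    mod <- modularity_optimal(make_net(A), n_iter = 60, seed = s)
    best <- bf_modularity_best(A)
    expect_equal(mod$Q, best, tolerance = 1e-9)
    # reported Q is the modularity of the reported partition
    expect_equal(mod$Q, modularity_of_partition(A, mod$partition),
                 tolerance = 1e-12)
  }
})

test_that("truncated power-law sampling and fitting recover parameters", {
  set.seed(6)
  deg <- sample_truncated_power_law(2000, a = 1.5, b = 4.0)
  fit <- fit_truncated_power_law(deg)
  expect_lt(abs(fit$a - 1.5), 0.2)
  expect_lt(abs(fit$b - 4.0) / 4.0, 0.2)
  expect_gt(fit$r_squared, 0.9)
  # regular graph: degenerate degree distribution refused
  K6 <- matrix(1L, 6, 6) - diag(1L, 6)
  expect_error(fit_truncated_power_law(make_net(K6)), "distinct degree")
})

test_that("random failure resilience has the closed-form anchors", {
  K <- make_net(matrix(1L, 100, 100) - diag(1L, 100))
  rc <- random_failure(K, fractions = c(0, 0.5), reps = 10, seed = 7)
  expect_equal(rc$relative_lcc[rc$fraction_removed == 0], 1)
  # remaining nodes of a complete graph always stay one component
  expect_equal(rc$relative_lcc[rc$fraction_removed == 0.5], 0.5)

  co <- generate_cohort(cohort_spec_tiny(seed = 8))
  rt <- residualize(co, "pooled_all")
  net <- binarize_at_density(association_matrix(rt, "HC"), 0.3)
  rc2 <- random_failure(net, fractions = seq(0, 0.8, 0.1), reps = 60,
                        seed = 9)
  # non-increasing within Monte-Carlo tolerance (2 SE ~ 2 * 0.5/sqrt(60))
  diffs <- diff(rc2$relative_lcc)
  expect_true(all(diffs < 2 * 0.5 / sqrt(60)))
})
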