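test_that("weights map to reciprocal distances with Inf for absent edges", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 2
  D <- weight_to_distance(W)
  expect_equal(D[1, 2], 0.5)
  expect_true(is.infinite(D[1, 3]))
  expect_equal(diag(D), rep(0, 3))
  # unit weights give hop counts as edge lengths
  expect_equal(weight_to_distance(unit_path3())[1, 2], 1)
})

test_that("weighted clustering matches closed forms on unit graphs", {
  K3 <- unit_complete(3)
  cc <- clustering_coefficient(K3)
  expect_equal(cc$nodal, rep(1, 3))
  expect_equal(cc$Cp, 1)
  expect_equal(clustering_coefficient(unit_path3())$Cp, 0)
  expect_equal(clustering_coefficient(unit_complete(4))$Cp, 1)
  # ring lattice closed form 3(K-2)/(4(K-1)) at K = 6
  W <- simulate_connectome(30, 6, 0, model = "lattice", seed = 1)
  expect_lt(abs(clustering_coefficient(W)$Cp - 3 * 4 / (4 * 5)), 1e-12)
})

test_that("characteristic path length averages finite shortest paths", {
  lp <- characteristic_path_length(unit_path3())
  expect_equal(lp$Lp, 4 / 3)
  expect_equal(lp$n_unreachable, 0)
  expect_equal(characteristic_path_length(unit_complete(5))$Lp, 1)
  # two disconnected unit edges on 4 nodes
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- W[3, 4] <- W[4, 3] <- 1
  lp <- characteristic_path_length(W)
  expect_equal(lp$Lp, 1)
  expect_equal(lp$n_unreachable, 4)  # unordered pairs
  expect_error(characteristic_path_length(matrix(0, 3, 3)), "no finite paths")
})

test_that("global efficiency is the mean reciprocal distance", {
  expect_equal(global_efficiency(unit_complete(4)), 1)
  expect_equal(global_efficiency(unit_path3()), 5 / 6)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_error(global_efficiency(matrix(0, 1, 1)), "2 nodes")
})

test_that("local efficiency scores neighbor-subgraph fault tolerance", {
  expect_equal(local_efficiency(unit_complete(4))$Eloc, 1)
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(local_efficiency(star)$Eloc, 0)
  expect_equal(local_efficiency(unit_path3())$Eloc, 0)
})

test_that("degree centrality supports strength and binary modes", {
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(degree_centrality(star), c(3, 1, 1, 1))
  K3w <- unit_complete(3) * 2
  expect_equal(degree_centrality(K3w, "strength"), rep(4, 3))
  expect_equal(degree_centrality(K3w, "binary"), rep(2, 3))
  expect_equal(degree_centrality(matrix(0, 3, 3))[2], 0)
})

test_that("betweenness credits interior nodes of shortest paths", {
  expect_equal(betweenness_centrality(unit_path3()), c(0, 1, 0))
  expect_equal(betweenness_centrality(unit_complete(5)), rep(0, 5))
})

test_that("mean-normalization rescales nodal vectors to mean one", {
  expect_equal(normalize_nodal(c(3, 1, 1, 1)), c(2, 2 / 3, 2 / 3, 2 / 3))
  expect_equal(normalize_nodal(rep(7, 5)), rep(1, 5))
  set.seed(3)
  for (i in 1:10) expect_equal(mean(normalize_nodal(runif(20, 0, 5) + 0.1)), 1)
  expect_error(normalize_nodal(rep(0, 4)), "all-zero")
})

test_that("hubs exceed the mean by more than one sample SD", {
  expect_equal(identify_hubs(c(3, 1, 1, 1)), 1L)
  expect_length(identify_hubs(rep(2, 6)), 0)
  v <- c(rep(1, 9), 5)
  expect_equal(identify_hubs(v), 10L)
})

test_that("null networks preserve degree sequence and weight multiset", {
  W <- ddtopo:::.as_weights(
    simulate_connectome(20, 4, 0.2, weights = "lognormal", seed = 31))
  ens <- generate_matched_nulls(W, n_nulls = 25, seed = 99)
  deg0 <- rowSums(W > 0)
  w0 <- sort(W[upper.tri(W) & W > 0])
  for (Wb in ens$networks) {
    expect_equal(rowSums(Wb > 0), deg0)
    expect_equal(sort(Wb[upper.tri(Wb) & Wb > 0]), w0, tolerance = 1e-12)
    expect_equal(Wb, t(Wb))
  }
  # network-mean nodal strength is preserved (weight multiset is identical)
  ms <- vapply(ens$networks, function(x) mean(rowSums(x)), numeric(1))
  expect_true(all(abs(ms - mean(rowSums(W))) < 1e-10))
})

test_that("null generation is deterministic given a seed", {
  W <- ddtopo:::.as_weights(simulate_connectome(15, 4, 0.3, seed = 5))
  e1 <- generate_matched_nulls(W, 5, seed = 7)
  e2 <- generate_matched_nulls(W, 5, seed = 7)
  e3 <- generate_matched_nulls(W, 5, seed = 8)
  expect_identical(e1$networks, e2$networks)
  expect_false(identical(e1$networks, e3$networks))
})

test_that("a complete graph cannot be rewired and warns", {
  W <- unit_complete(6)
  expect_warning(ens <- generate_matched_nulls(W, 3, seed = 1), "complete")
  for (Wb in ens$networks) expect_equal((Wb > 0) * 1, (W > 0) * 1)
})

test_that("self-normalization gives gamma = lambda = sigma = 1", {
  W <- ddtopo:::.as_weights(simulate_connectome(20, 4, 0.2, seed = 13))
  sw <- small_worldness(W, list(W))
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
})

test_that("density-matched random graphs self-normalize to sigma near 1", {
  W <- simulate_connectome(90, 8, model = "random", seed = 17)
  ens <- generate_matched_nulls(W, 100, seed = 18)
  sw <- small_worldness(W, ens)
  expect_gt(sw$sigma, 0.8)
  expect_lt(sw$sigma, 1.2)
})

test_that("rescaling weights leaves topology-only quantities unchanged", {
  W <- ddtopo:::.as_weights(
    simulate_connectome(24, 6, 0.15, weights = "lognormal", seed = 41))
  c_scale <- 3.7
  W2 <- W * c_scale
  e1 <- generate_matched_nulls(W, 20, seed = 5)
  e2 <- generate_matched_nulls(W2, 20, seed = 5)
  s1 <- small_worldness(W, e1)
  s2 <- small_worldness(W2, e2)
  expect_equal(s2$gamma, s1$gamma, tolerance = 1e-10)
  expect_equal(s2$lambda, s1$lambda, tolerance = 1e-10)
  expect_equal(s2$sigma, s1$sigma, tolerance = 1e-10)
  # Lp scales by 1/c, Eglob by c under d = 1/W
  expect_equal(characteristic_path_length(W2)$Lp,
               characteristic_path_length(W)$Lp / c_scale)
  expect_equal(global_efficiency(W2), global_efficiency(W) * c_scale)
  # betweenness ranking is scale-free
  expect_equal(order(betweenness_centrality(W2)),
               order(betweenness_centrality(W)))
})

test_that("shortest-path metrics agree with the Floyd-Warshall oracle", {
  set.seed(52)
  for (g in 1:20) {
    W <- rand_wgraph(sample(4:8, 1), p = 0.6, unit = (g %% 4 == 0))
    expect_equal(characteristic_path_length(W)$Lp, fw_lp(W),
                 tolerance = 1e-10)
    expect_equal(global_efficiency(W), fw_eglob(W), tolerance = 1e-10)
    expect_equal(betweenness_centrality(W), fw_betweenness(W),
                 tolerance = 1e-10)
  }
})

test_that("topology report assembles consistent global and nodal tables", {
  W <- simulate_connectome(30, 6, 0.15, weights = "lognormal", seed = 61)
  rep1 <- topology_report(W, subject_id = "s1", n_nulls = 20, seed = 3)
  expect_equal(nrow(rep1$global), 1)
  expect_equal(nrow(rep1$nodal), 30)
  expect_equal(mean(rep1$nodal$degree_norm), 1)
  expect_true(all(rep1$nodal$is_hub_degree %in% c(TRUE, FALSE)))
  expect_gt(rep1$global$sigma, 0)
  # determinism
  rep2 <- topology_report(W, subject_id = "s1", n_nulls = 20, seed = 3)
  expect_identical(rep1, rep2)
})
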