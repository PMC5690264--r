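test_that("lattice maps have the right geometry and ground-truth adjacency", {
  sm <- generate_lattice_map(synthetic_scenario(n_rows = 3, n_cols = 3, seed = 1))
  expect_length(sm$map$area_ids, 9)
  # centre cell of a 3x3 queen lattice touches all 8 others
  expect_length(sm$true_adjacency$neighbors[[5]], 8)
  expect_equal(sum(sm$true_adjacency$num), 40)

  sm2 <- generate_lattice_map(synthetic_scenario(n_rows = 2, n_cols = 1, seed = 1))
  expect_length(sm2$map$area_ids, 2)
  expect_equal(sum(sm2$true_adjacency$num), 2)  # one shared edge, one pair

  expect_error(synthetic_scenario(n_rows = 0, n_cols = 3), "positive")
  expect_error(synthetic_scenario(jitter_fraction = 1.5), "jitter_fraction")
  expect_error(synthetic_scenario(nu_s_true = 0), "positive")
})

test_that("the generative pipeline is bit-identical under a fixed seed", {
  sc <- synthetic_scenario(n_rows = 4, n_cols = 4, jitter_fraction = 0.2, seed = 99)
  d1 <- simulate_scenario(sc)
  d2 <- simulate_scenario(sc)
  expect_identical(d1$map$map$polygons, d2$map$map$polygons)
  expect_identical(d1$table$Y, d2$table$Y)
  expect_identical(d1$truth, d2$truth)
  # a different seed changes the data
  d3 <- simulate_scenario(synthetic_scenario(n_rows = 4, n_cols = 4,
                                             jitter_fraction = 0.2, seed = 100))
  expect_false(identical(d1$table$Y, d3$table$Y))
})

test_that("population generation respects the range and the low-population rule", {
  sc <- synthetic_scenario(n_rows = 3, n_cols = 3,
                           population_range = c(7, 7), low_pop_fraction = 0,
                           seed = 2)
  tab <- generate_population(generate_lattice_map(sc), sc)
  expect_true(all(tab$N == 7))

  sc2 <- synthetic_scenario(n_rows = 10, n_cols = 10, low_pop_fraction = 0.05,
                            low_pop_floor = 10, seed = 3)
  tab2 <- generate_population(generate_lattice_map(sc2), sc2)
  totals <- area_totals(tab2)$N
  expect_equal(sum(totals < 10), 5)  # exactly 5 of 100 areas below the floor

  # reproducible
  tab3 <- generate_population(generate_lattice_map(sc2), sc2)
  expect_identical(tab2$N, tab3$N)
})

test_that("ICAR draws follow the constrained-Gaussian law", {
  # every draw satisfies the sum-to-zero constraint
  g <- toy_weighted_graph()
  S <- simulate_icar(g$adj, g$ws, 0.5, seed = 1, n_draws = 50)
  expect_true(all(abs(rowSums(S)) < 1e-10))

  # 2-node model: S = (d/2, -d/2) and Var(d) equals the ICAR variance
  # (pairwise density exp(-w (s1 - s2)^2 / (2 nu)) => d ~ Normal(0, nu))
  a2 <- adjacency_list(list(2L, 1L))
  S2 <- simulate_icar(a2, equal_weights(a2), 1, seed = 42, n_draws = 10000)
  expect_equal(S2[, 1], -S2[, 2])
  expect_lt(abs(var(S2[, 1] - S2[, 2]) - 1), 0.05)

  # 4-node toy: sample covariance matches variance * pinv(weight Laplacian)
  Q <- weight_laplacian(g$ws)
  eg <- eigen(Q, symmetric = TRUE)
  V <- eg$vectors[, 1:3]
  pinvQ <- V %*% diag(1 / eg$values[1:3]) %*% t(V)
  S4 <- simulate_icar(g$adj, g$ws, 0.7, seed = 7, n_draws = 100000)
  expect_lt(max(abs(cov(S4) - 0.7 * pinvQ)), 0.01)

  # disconnected graph is rejected
  disc <- adjacency_list(list(2L, 1L, 4L, 3L))
  expect_error(simulate_icar(disc, equal_weights(disc), 1), "disconnected")
})

test_that("count simulation follows the Poisson offset model", {
  set.seed(1)
  E <- rep(1, 10000)
  # null model: mean(Y)/E ~ 1
  Y0 <- simulate_counts(E, seed = 5)
  expect_lt(abs(mean(Y0) - 1), 3 * sqrt(1 / 10000))
  # alpha = log 2 doubles the mean (Poisson moments, 3 sd band)
  Y2 <- simulate_counts(E, alpha = log(2), seed = 6)
  expect_lt(abs(mean(Y2) - 2), 3 * sqrt(2 / 10000))
  # zero expected count forces zero counts
  expect_identical(simulate_counts(c(0, 0, 5), alpha = 10, seed = 7)[1:2], c(0L, 0L))
  expect_error(simulate_counts(c(-1, 2)), "nonnegative")
})

test_that("vertex jitter breaks exact-match adjacency and tolerance recovers it", {
  sc <- synthetic_scenario(n_rows = 10, n_cols = 10, jitter_fraction = 0.1,
                           vertex_jitter_sd = 1e-3, seed = 7)
  sm <- generate_lattice_map(sc)
  exact <- extract_queen_adjacency(sm$map, tolerance = 0)
  expect_lt(sum(exact$num), sum(sm$true_adjacency$num))
  recovered <- extract_queen_adjacency(sm$map, tolerance = sm$jitter$magnitude)
  expect_identical(recovered$neighbors, sm$true_adjacency$neighbors)
})

test_that("synthetic datasets round-trip through their on-disk formats", {
  d <- simulate_scenario(synthetic_scenario(n_rows = 3, n_cols = 4, seed = 11))
  dir <- withr::local_tempdir()
  write_synthetic_dataset(d, dir)
  expect_true(all(file.exists(file.path(dir, c("map.geojson", "strata.csv",
                                               "covariates.csv",
                                               "adjacency_true.txt",
                                               "truth.json")))))
  map2 <- read_area_map_geojson(file.path(dir, "map.geojson"))
  expect_identical(map2$area_ids, d$map$map$area_ids)
  expect_equal(map2$polygons, d$map$map$polygons)
  tab2 <- read_stratum_table(file.path(dir, "strata.csv"),
                             area_order = map2$area_ids)
  expect_equal(tab2$N, d$table$N)
  expect_equal(tab2$Y, d$table$Y)
})
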