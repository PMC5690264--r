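test_that("the ICAR conditional is the weighted neighbour average", {
  chain <- chain_adjacency(3)
  ws <- equal_weights(chain)
  # middle area, equal weights, neighbours at 0.2 and 0.4
  cond <- icar_conditional(2, c(0.2, 0, 0.4), ws, nu_s = 0.6)
  expect_equal(cond$mean, 0.3)
  expect_equal(cond$variance, 0.3)
  # single neighbour: the conditional mean is that neighbour's value
  cond1 <- icar_conditional(1, c(0, 0.7, 0), ws, nu_s = 1)
  expect_equal(cond1$mean, 0.7)
  # weights (1, 3) on neighbours at 0 and 0.4
  wsv <- weight_spec(chain_adjacency(3), c(1, 3))
  expect_equal(icar_conditional(2, c(0, 0, 0.4), wsv, 2)$mean, 0.3)
  expect_equal(icar_conditional(2, c(0, 0, 0.4), wsv, 2)$variance, 0.5)
  # doubling weights and the variance together leaves the conditional alone
  ws2 <- weight_spec(chain_adjacency(3), 2 * c(1, 3))
  expect_equal(icar_conditional(2, c(0, 0, 0.4), ws2, 4),
               icar_conditional(2, c(0, 0, 0.4), wsv, 2))
})

test_that("conditionals derived by brute force from the joint density match", {
  # energy E(s_i) is quadratic; evaluating the joint pairwise-difference
  # density at s_i = 0, 1, 2 recovers its coefficients exactly, giving the
  # conditional mean and variance with no use of the conditional formula
  set.seed(3)
  graphs <- list(
    list(adj = chain_adjacency(3), values = c(1, 1, 1)),
    list(adj = toy_weighted_graph()$adj, values = c(1, 2, 3, 4)),
    list(adj = extract_queen_adjacency(unit_grid_map(2, 2), 0),
         values = runif(4, 0.5, 2)))
  for (g in graphs) {
    ws <- product_weights(g$adj, g$values)
    n <- g$adj$n
    nu <- 0.37
    S <- rnorm(n)
    energy <- function(i, si) {
      St <- S; St[i] <- si
      sum(ws$w * (St[ws$pairs[, 1]] - St[ws$pairs[, 2]])^2) / (2 * nu)
    }
    for (i in seq_len(n)) {
      e0 <- energy(i, 0); e1 <- energy(i, 1); e2 <- energy(i, 2)
      a <- (e2 - 2 * e1 + e0) / 2
      b <- e1 - e0 - a
      cond <- icar_conditional(i, S, ws, nu)
      expect_equal(-b / (2 * a), cond$mean, tolerance = 1e-10)
      expect_equal(1 / (2 * a), cond$variance, tolerance = 1e-10)
    }
  }
})

test_that("model construction validates its inputs", {
  chain <- chain_adjacency(3)
  ws <- equal_weights(chain)
  # no covariates is fine
  expect_s3_class(bym_model(c(1L, 2L, 0L), c(1, 2, 1), ws), "bym_model")
  # islands are named
  isl <- adjacency_list(list(2L, 1L, integer(0)), area_ids = c("a", "b", "far"))
  expect_error(bym_model(c(1L, 1L, 1L), rep(1, 3), equal_weights(isl)), "far")
  # a single area has no ICAR model
  one_pair <- adjacency_list(list(integer(0)))
  expect_error(bym_model(1L, 1, equal_weights(one_pair)), "single area")
  # negative counts
  expect_error(bym_model(c(-1L, 1L, 1L), rep(1, 3), ws), "negative")
  # disconnected maps are rejected
  disc <- adjacency_list(list(2L, 1L, 4L, 3L))
  expect_error(bym_model(rep(1L, 4), rep(1, 4), equal_weights(disc)),
               "disconnected")
  # zero expected counts floored with a warning naming the area
  expect_warning(m <- bym_model(c(1L, 0L, 1L), c(1, 0, 1), ws), "floored")
  expect_equal(m$E[2], 1e-4)
})

test_that("a null fit recovers flat risks", {
  sm <- generate_lattice_map(synthetic_scenario(n_rows = 5, n_cols = 5, seed = 1))
  E <- rep(20, 25)
  fit <- quiet_fit(bym_model(rep(20L, 25), E, equal_weights(sm$true_adjacency)),
                   sampler_config(seed = 4))
  pm <- colMeans(risk_draws(fit))
  expect_true(all(pm > 0.8 & pm < 1.2))
  # every retained iteration keeps the sum-to-zero constraint
  S <- do.call(rbind, lapply(fit$chains, function(ch) ch$S))
  expect_lt(max(abs(rowSums(S))), 1e-8)
})

test_that("chains are bit-identical under the same seed and differ otherwise", {
  d <- simulate_scenario(synthetic_scenario(n_rows = 4, n_cols = 4, seed = 2))
  tot <- area_totals(d$table)
  E <- unname(expected_counts(d$table))
  m <- bym_model(tot$Y, E, equal_weights(d$map$true_adjacency), X = d$X)
  cfg <- sampler_config(burn_in = 500, keep = 500, seed = 77)
  f1 <- quiet_fit(m, cfg)
  f2 <- quiet_fit(m, cfg)
  expect_identical(f1$chains, f2$chains)
  f3 <- quiet_fit(m, sampler_config(burn_in = 500, keep = 500, seed = 78))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("equal weights and unit product weights give identical chains", {
  d <- simulate_scenario(synthetic_scenario(n_rows = 4, n_cols = 4, seed = 3))
  tot <- area_totals(d$table)
  E <- unname(expected_counts(d$table))
  adj <- d$map$true_adjacency
  cfg <- sampler_config(burn_in = 300, keep = 300, seed = 5)
  f_eq <- quiet_fit(bym_model(tot$Y, E, equal_weights(adj)), cfg)
  f_pr <- quiet_fit(bym_model(tot$Y, E, product_weights(adj, rep(1, adj$n))), cfg)
  expect_identical(f_eq$chains, f_pr$chains)
})

test_that("the precision Gibbs update matches its Gamma full conditional", {
  g <- toy_weighted_graph()
  S <- c(0.5, -0.2, 0.1, -0.4)
  pr <- g$ws$pairs
  a <- 0.5; b <- 5e-4
  set.seed(31)
  tau <- bymweights:::tau_s_gibbs_draws(S, pr[, 1] - 1L, pr[, 2] - 1L, g$ws$w,
                                        a, b, 20000)
  shape <- a + (4 - 1) / 2
  rate <- b + 0.5 * sum(g$ws$w * (S[pr[, 1]] - S[pr[, 2]])^2)
  expect_lt(abs(mean(tau) / (shape / rate) - 1), 0.03)
  expect_lt(abs(var(tau) / (shape / rate^2) - 1), 0.06)
})

test_that("the Gamma precision hyperprior implies the documented sd prior", {
  p <- implied_sd_prior(0.5, 0.0005)
  expect_equal(round(p$median_sd, 2), 0.05)
  # scaling the rate by c scales the median sd by sqrt(c)
  p4 <- implied_sd_prior(0.5, 4 * 0.0005)
  expect_equal(p4$median_sd, 2 * p$median_sd, tolerance = 1e-12)
  expect_error(implied_sd_prior(0, 1), "positive")
  expect_error(implied_sd_prior(1, -1), "positive")
})

test_that("chain export writes draws and metadata", {
  d <- simulate_scenario(synthetic_scenario(n_rows = 3, n_cols = 3, seed = 6))
  tot <- area_totals(d$table)
  fit <- quiet_fit(bym_model(tot$Y, unname(expected_counts(d$table)),
                             equal_weights(d$map$true_adjacency), X = d$X),
                   sampler_config(burn_in = 200, keep = 100, seed = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_chains(fit, f)
  out <- read.csv(f)
  expect_equal(nrow(out), 200)  # 2 chains x 100 retained
  expect_true(all(c("alpha", "nu_s", "nu_u", "S_1", "U_9") %in% names(out)))
  meta <- jsonlite::read_json(paste0(f, ".meta.json"))
  expect_equal(meta$scheme_label, "equal")
})
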