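test_that("the Gelman-Rubin statistic behaves at its reference points", {
  set.seed(10)
  x <- rnorm(1000)
  # identical chains: B = 0, clipped to 1
  expect_equal(gelman_rubin(cbind(x, x)), 1)
  # disjoint chains are flagged loudly
  expect_gt(gelman_rubin(cbind(rnorm(1000), rnorm(1000, 10))), 3)
  # chains from the same distribution sit near 1
  expect_lt(gelman_rubin(cbind(rnorm(5000), rnorm(5000))), 1.05)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("batch-means MC error scales like an effective sample size", {
  set.seed(11)
  x <- rnorm(1e5)
  r <- mc_error(x)
  expect_lt(r$ratio, 0.05)
  expect_lt(abs(r$mcse / (sd(x) / sqrt(1e5)) - 1), 0.5)
  # constant chain
  expect_equal(mc_error(rep(2, 100))$mcse, 0)
  expect_equal(mc_error(rep(2, 100))$ratio, 0)
  # autocorrelation inflates the ratio relative to iid at the same length
  ar <- as.numeric(arima.sim(list(ar = 0.9), 1e4))
  iid <- rnorm(1e4)
  expect_gt(mc_error(ar)$ratio, mc_error(iid)$ratio)
  expect_error(mc_error(rnorm(10)), "too short")
})

test_that("DIC decomposes into fit and complexity", {
  # degenerate posterior: every draw identical, so pD = 0 and DIC = Dhat
  Y <- c(3L, 1L, 4L)
  lam <- matrix(rep(c(2.5, 1.2, 3.8), each = 50), nrow = 50)
  d <- dic(lam, Y = Y)
  expect_equal(d$pD, 0, tolerance = 1e-10)
  expect_equal(d$DIC, d$Dbar)

  # Poisson-gamma conjugate toy (n = 1): pD has a closed form
  # lambda | Y ~ Gamma(a0 + Y, b0 + 1); pD = 2 Y (log(mean) - E log lambda)
  a0 <- 2; b0 <- 1; Yobs <- 7L
  ap <- a0 + Yobs; bp <- b0 + 1
  set.seed(12)
  draws <- matrix(rgamma(1e5, ap, bp), ncol = 1)
  d2 <- dic(draws, Y = Yobs)
  pD_exact <- 2 * Yobs * (log(ap / bp) - (digamma(ap) - log(bp)))
  expect_lt(abs(d2$pD / pD_exact - 1), 0.1)

  expect_error(dic(matrix(numeric(0), 0, 1), Y = 1L), "no draws")
})

test_that("risk summaries match a direct sort oracle", {
  set.seed(13)
  r <- cbind(rlnorm(500), rlnorm(500, 0.5))
  s <- summarize_risks(r)
  expect_equal(s$per_area$median[1], unname(quantile(r[, 1], 0.5)))
  expect_equal(s$per_area$q2.5[2], unname(quantile(r[, 2], 0.025)))
  expect_true(s$region[["min"]] <= s$region[["median"]])
  expect_true(s$region[["median"]] <= s$region[["max"]])

  ones <- matrix(1, 100, 3)
  s1 <- summarize_risks(ones)
  expect_equal(s1$per_area$mean, rep(1, 3))
  expect_equal(s1$per_area$q2.5, rep(1, 3))
  expect_equal(s1$per_area$q97.5, rep(1, 3))
})

test_that("exceedance probabilities use a strict threshold", {
  # area 1: all draws above 1; area 2: exactly half; area 3: none
  r <- cbind(rep(2, 10), rep(c(2, 0.5), 5), rep(0.5, 10))
  ex <- exceedance_probabilities(r, thresholds = c(0.5, 0.75, 0.9, 0.95))
  expect_equal(ex$prob, c(1, 0.5, 0))
  # the area sitting exactly at 0.50 is NOT counted at that threshold
  expect_equal(unname(ex$counts), c(1L, 1L, 1L, 1L))

  # hand-built draws with known exceedance fractions
  set.seed(14)
  p_true <- c(0.9, 0.6, 0.2)
  r2 <- sapply(p_true, function(p) ifelse(runif(2000) < p, 1.5, 0.5))
  ex2 <- exceedance_probabilities(r2, thresholds = c(0.5))
  expect_equal(ex2$prob, p_true, tolerance = 0.05)
  expect_equal(unname(ex2$counts), 2L)
})

test_that("the spatial fraction reflects the S/U balance", {
  n <- 50; iters <- 200
  set.seed(15)
  S <- matrix(rnorm(iters * n), iters)
  Z <- matrix(0, iters, n)
  expect_equal(spatial_fraction(fake_fit(S, Z))$mean, 1)
  expect_equal(spatial_fraction(fake_fit(Z, S))$mean, 0)
  # S and U iid from the same distribution: fraction near 1/2
  U <- matrix(rnorm(iters * n), iters)
  expect_equal(spatial_fraction(fake_fit(S, U))$mean, 0.5, tolerance = 0.02)
})
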