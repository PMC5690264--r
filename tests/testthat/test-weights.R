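test_that("equal weights give unit pair weights and degree totals", {
  grid <- extract_queen_adjacency(unit_grid_map(3, 3), 0)
  ws <- equal_weights(grid)
  expect_equal(ws$w_plus[5], 8)          # centre cell
  expect_true(all(ws$w == 1))
  chain <- chain_adjacency(3)
  expect_equal(equal_weights(chain)$w_plus, c(1, 2, 1))
})

test_that("product weights implement w_ij = values_i * values_j with a floor", {
  chain <- chain_adjacency(3)
  ws <- product_weights(chain, c(2, 3, 4))
  expect_equal(ws$w, c(6, 12))
  expect_equal(ws$w_plus, c(6, 18, 12))

  # values identically one reduce to equal weights
  ws1 <- product_weights(chain, c(1, 1, 1))
  expect_equal(ws1$w, equal_weights(chain)$w)
  expect_equal(ws1$w_plus, equal_weights(chain)$w_plus)

  # a zero-valued area gets floored weights; w_plus stays positive
  wsz <- suppressMessages(product_weights(chain, c(0, 3, 4), floor = 1e-6))
  expect_equal(wsz$w, c(1e-6, 12))
  expect_true(all(wsz$w_plus > 0))

  expect_error(product_weights(chain, c(-1, 2, 3)), "nonnegative")
  expect_error(product_weights(chain, c(1, 2)), "one value per area")
})

test_that("row normalisation is row-stochastic and scale invariant", {
  g <- toy_weighted_graph()
  rows <- normalized_rows(g$ws)
  expect_true(all(abs(vapply(rows, sum, numeric(1)) - 1) < 1e-12))

  # chain weights (6, 12): middle row splits 1/3, 2/3
  ws <- product_weights(chain_adjacency(3), c(2, 3, 4))
  expect_equal(normalized_rows(ws)[[2]], c(1 / 3, 2 / 3))

  # equal weights with 4 neighbours: each normalised weight is 1/4
  grid <- extract_queen_adjacency(unit_grid_map(2, 2), 0)
  expect_equal(normalized_rows(equal_weights(grid))[[1]], rep(1 / 3, 3))

  # rescaling the value vector by c > 0 leaves normalised rows unchanged
  r1 <- normalized_rows(product_weights(g$adj, c(1, 2, 3, 4)))
  r2 <- normalized_rows(product_weights(g$adj, 17.3 * c(1, 2, 3, 4)))
  expect_equal(r1, r2)

  # islands are reported by name
  isl <- adjacency_list(list(2L, 1L, integer(0)), area_ids = c("a", "b", "lonely"))
  ws_isl <- weight_spec(isl, 1)
  expect_error(normalized_rows(ws_isl), "lonely")
})

test_that("weight specs validate symmetry inputs and recompute totals", {
  chain <- chain_adjacency(3)
  expect_error(weight_spec(chain, c(1, -2)), "positive")
  expect_error(weight_spec(chain, c(1, 2, 3)), "one weight per adjacent pair")
  ws <- weight_spec(chain, c(5, 7))
  expect_equal(ws$w_plus, c(5, 12, 7))
})
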