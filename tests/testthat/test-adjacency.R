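test_that("queen extraction on a unit grid matches grid combinatorics", {
  adj <- extract_queen_adjacency(unit_grid_map(3, 3), tolerance = 0)
  deg <- adj$num
  corner <- c(1, 3, 7, 9); edge <- c(2, 4, 6, 8)
  expect_true(all(deg[corner] == 3))
  expect_true(all(deg[edge] == 5))
  expect_equal(deg[5], 8L)
  expect_equal(sum(deg), 40)
  expect_error(extract_queen_adjacency(unit_grid_map(2, 2), tolerance = -1),
               "nonnegative")
})

test_that("corner-touching squares are queen neighbors, within tolerance", {
  sq <- function(x0, y0) rbind(c(x0, y0), c(x0 + 1, y0), c(x0 + 1, y0 + 1),
                               c(x0, y0 + 1), c(x0, y0))
  touching <- area_map(c("a", "b"), list(sq(0, 0), sq(1, 1)))
  expect_equal(sum(extract_queen_adjacency(touching, 0)$num), 2)

  # same squares, but the shared corner recorded as two points 1e-4 apart
  b_off <- sq(1, 1); b_off[c(1, 5), 1] <- b_off[c(1, 5), 1] + 1e-4
  off <- area_map(c("a", "b"), list(sq(0, 0), b_off))
  expect_equal(sum(extract_queen_adjacency(off, 1e-6)$num), 0)
  expect_equal(sum(extract_queen_adjacency(off, 1e-3)$num), 2)
})

test_that("tolerance is monotone and results are always symmetric", {
  sc <- synthetic_scenario(n_rows = 6, n_cols = 6, jitter_fraction = 0.3,
                           vertex_jitter_sd = 5e-3, seed = 21)
  sm <- generate_lattice_map(sc)
  tols <- c(0, 1e-4, 5e-3, 2e-2)
  prev <- NULL
  for (tol in tols) {
    adj <- extract_queen_adjacency(sm$map, tol)
    for (i in seq_len(adj$n)) for (j in adj$neighbors[[i]])
      expect_true(i %in% adj$neighbors[[j]])
    if (!is.null(prev))
      for (i in seq_len(adj$n))
        expect_true(all(prev$neighbors[[i]] %in% adj$neighbors[[i]]))
    prev <- adj
  }
  # unjittered lattice at tolerance 0 equals the ground truth exactly
  sm0 <- generate_lattice_map(synthetic_scenario(n_rows = 6, n_cols = 6, seed = 21))
  expect_identical(extract_queen_adjacency(sm0$map, 0)$neighbors,
                   sm0$true_adjacency$neighbors)
})

test_that("adjacency lists enforce symmetry and no self-loops", {
  expect_error(adjacency_list(list(2L, integer(0))), "asymmetric")
  expect_error(adjacency_list(list(c(1L, 2L), 1L)), "self-adjacency")
  a <- adjacency_list(list(2L, c(1L, 3L), 2L))
  expect_equal(a$num, c(1L, 2L, 1L))
  expect_equal(a$adj, c(2L, 1L, 3L, 2L))
})

test_that("adjacency audits count directed entries and the undercount error", {
  a <- chain_adjacency(4)
  same <- compare_adjacency(a, a)
  expect_equal(same$undercount_error, 0)
  expect_equal(nrow(same$missing_pairs), 0)
  expect_equal(nrow(same$extra_pairs), 0)

  # true pairs {(1,2),(2,3)} vs generated {(1,2)}: 4 vs 2 directed entries
  t2 <- adjacency_from_pairs(3, rbind(c(1, 2), c(2, 3)))
  g2 <- adjacency_from_pairs(3, rbind(c(1, 2)))
  rep2 <- compare_adjacency(t2, g2)
  expect_equal(rep2$total_true, 4)
  expect_equal(rep2$total_generated, 2)
  expect_equal(rep2$undercount_error, 0.5)
  expect_equal(nrow(rep2$missing_pairs), 1)

  expect_error(compare_adjacency(t2, chain_adjacency(4)), "different numbers")
})

test_that("WinBUGS files round-trip adjacency and weights", {
  a <- chain_adjacency(3)
  txt <- write_winbugs_adjacency(a)
  expect_match(txt, "num = c(1, 2, 1)", fixed = TRUE)
  expect_match(txt, "adj = c(2, 1, 3, 2)", fixed = TRUE)
  expect_match(txt, "sumNumNeigh = 4", fixed = TRUE)

  # random symmetric graph with weights: read(write(x)) = x
  set.seed(8)
  sm <- generate_lattice_map(synthetic_scenario(n_rows = 4, n_cols = 3, seed = 5))
  adj <- sm$true_adjacency
  ws <- product_weights(adj, runif(adj$n, 1, 10))
  f <- withr::local_tempfile(fileext = ".txt")
  write_winbugs_adjacency(adj, ws, f)
  back <- read_winbugs_adjacency(f)
  expect_identical(back$adjacency$neighbors, adj$neighbors)
  expect_equal(back$weights$w, ws$w)
  expect_equal(back$weights$w_plus, ws$w_plus)

  # an island (num = 0) survives serialisation; the model rejects it later
  island <- adjacency_list(list(2L, 1L, integer(0)))
  back2 <- read_winbugs_adjacency(write_winbugs_adjacency(island))
  expect_equal(back2$adjacency$num, c(1L, 1L, 0L))
  expect_error(bym_model(c(1L, 1L, 1L), c(1, 1, 1), equal_weights(back2$adjacency)),
               "island")

  # inconsistent lengths are rejected
  expect_error(read_winbugs_adjacency("list(num = c(2, 1), adj = c(2))"),
               "sum\\(num\\)")
  expect_error(read_winbugs_adjacency(
    "list(num = c(1, 1), adj = c(2, 1), weights = c(1))"), "weight count")
})

test_that("CSV edge lists round-trip weight specifications", {
  g <- toy_weighted_graph()
  f <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(g$ws, f)
  back <- read_edge_list(f, n = 4)
  expect_equal(back$w, g$ws$w)
  expect_identical(back$adjacency$neighbors, g$adj$neighbors)
})
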