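# shared fixtures built in code

# exact unit-square grid map (no displacement, no jitter)
unit_grid_map <- function(nr, nc) {
  polys <- list()
  ids <- character(0)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ring <- rbind(c(j - 1, i - 1), c(j, i - 1), c(j, i), c(j - 1, i),
                  c(j - 1, i - 1))
    polys <- c(polys, list(ring))
    ids <- c(ids, sprintf("g%02d%02d", i, j))
  }
  area_map(ids, polys)
}

# 1 - 2 - 3 - ... - n chain adjacency
chain_adjacency <- function(n) {
  nb <- lapply(seq_len(n), function(i)
    c(if (i > 1) i - 1L, if (i < n) i + 1L))
  adjacency_list(nb)
}

# small connected weighted graph for ICAR oracles
toy_weighted_graph <- function() {
  adj <- adjacency_list(list(c(2L, 3L), c(1L, 3L, 4L), c(1L, 2L), 2L))
  list(adj = adj, ws = product_weights(adj, c(1, 2, 3, 4)))
}

# dense weight Laplacian of a weight_spec
weight_laplacian <- function(ws) {
  n <- ws$adjacency$n
  Q <- matrix(0, n, n)
  pr <- ws$pairs
  Q[pr] <- -ws$w
  Q[pr[, 2:1, drop = FALSE]] <- -ws$w
  diag(Q) <- ws$w_plus
  Q
}

# minimal bym_fit-shaped object from given draw matrices (for diagnostics)
fake_fit <- function(S, U, alpha = rep(0, nrow(S)), beta = NULL) {
  if (is.null(beta)) beta <- matrix(numeric(0), nrow(S), 0)
  structure(list(chains = list(list(alpha = alpha, beta = beta, S = S, U = U,
                                    nu_s = rep(1, nrow(S)),
                                    nu_u = rep(1, nrow(S)))),
                 model = list(X = matrix(numeric(0), ncol(S), 0))),
            class = "bym_fit")
}

quiet_fit <- function(...) suppressWarnings(suppressMessages(run_mcmc(...)))
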