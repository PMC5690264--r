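#' Define a synthetic small-area scenario
#'
#' A scenario fixes everything the synthetic generator needs to emulate a
#' senior-falls small-area study: an irregular lattice map whose shared
#' vertices can be stored with discrepant coordinates (the digitisation
#' failure mode that breaks exact-match adjacency extraction), a stratified
#' senior population over 2 sexes x 5 age groups with a configurable share
#' of near-empty areas, spatially structured covariates, and a Poisson BYM
#' outcome with known intercept, coefficients, and spatial/unstructured
#' variance components under a chosen true weight scheme.
#'
#' Default stratum rates rise with age with roughly a five-fold ratio
#' between the 85+ and 65-69 groups, mirroring the age gradient of fall
#' injuries over a multi-year study window.
#'
#' @param n_rows,n_cols lattice dimensions (>= 2 each for a connected
#'   non-trivial map).
#' @param vertex_jitter_sd sd (map units) of the Normal perturbation applied
#'   independently per polygon to duplicated shared vertices.
#' @param jitter_fraction proportion in `[0, 1]` of shared vertices stored
#'   with perturbed duplicate coordinates.
#' @param displacement_sd sd of the smooth random displacement of lattice
#'   vertices that makes areas irregular (applied consistently, so it does
#'   not break adjacency); clamped at 0.3 cell units.
#' @param stratum_rates named vector of 10 per-stratum event rates in
#'   `[0, 1]` (names `"sex:age_group"`).
#' @param population_range integer min/max seniors per area per stratum.
#' @param population_gradient proportion in `[0, 1]` of the population
#'   range modulated by the spatial pattern (0 = spatially uniform draws
#'   over the whole range; towards 1, "rural" areas draw from the bottom of
#'   the range and "urban" areas from the full range, emulating the strong
#'   urban-rural structure of senior populations). Draws always stay
#'   within `population_range`.
#' @param population_pattern `"gradient"` for a smooth diagonal
#'   urban-rural surface, or `"patchy"` for interleaved high- and
#'   low-population areas (half the areas at random), the regime in which
#'   areas with high and low population-at-risk sit next to each other.
#' @param low_pop_fraction fraction of areas forced to near-zero total
#'   population-at-risk.
#' @param low_pop_floor low-population areas get total `N_i` strictly below
#'   this count.
#' @param alpha_true,beta_true true intercept and regression coefficients
#'   (one spatially structured standardized covariate per coefficient).
#' @param nu_s_true,nu_u_true true variances of the spatial (ICAR) and
#'   unstructured random effects; must be positive.
#' @param weight_scheme_true weight scheme generating the spatial effects:
#'   `"equal"`, `"population"`, `"density"`, or `"expected"`.
#' @param seed master integer seed; per-stage streams are derived from it,
#'   and identical scenario + seed gives bit-identical output.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_rows = 10, n_cols = 10,
                               vertex_jitter_sd = 1e-3,
                               jitter_fraction = 0,
                               displacement_sd = 0.12,
                               stratum_rates = default_stratum_rates(),
                               population_range = c(10, 60),
                               population_gradient = 0.7,
                               population_pattern = c("gradient", "patchy"),
                               low_pop_fraction = 0.05,
                               low_pop_floor = 10,
                               alpha_true = 0,
                               beta_true = c(0.3, 0.02),
                               nu_s_true = 0.3,
                               nu_u_true = 0.05,
                               weight_scheme_true = c("equal", "population",
                                                      "density", "expected"),
                               seed = 1L) {
  weight_scheme_true <- match.arg(weight_scheme_true)
  population_pattern <- match.arg(population_pattern)
  if (n_rows < 1 || n_cols < 1 || n_rows * n_cols < 2)
    stop_config("lattice must have positive dimensions and at least 2 areas")
  if (jitter_fraction < 0 || jitter_fraction > 1)
    stop_config("jitter_fraction must be in [0, 1]")
  if (vertex_jitter_sd < 0) stop_config("vertex_jitter_sd must be >= 0")
  if (length(stratum_rates) != 10 || any(stratum_rates < 0 | stratum_rates > 1))
    stop_config("stratum_rates must be 10 rates in [0, 1]")
  if (nu_s_true <= 0 || nu_u_true <= 0) stop_config("variances must be positive")
  if (low_pop_fraction < 0 || low_pop_fraction > 1)
    stop_config("low_pop_fraction must be in [0, 1]")
  if (population_gradient < 0 || population_gradient > 1)
    stop_config("population_gradient must be in [0, 1]")
  population_range <- as.integer(population_range)
  if (length(population_range) != 2 || population_range[1] < 0 ||
      population_range[2] < population_range[1])
    stop_config("population_range must be nondecreasing nonnegative min/max")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 vertex_jitter_sd = vertex_jitter_sd,
                 jitter_fraction = jitter_fraction,
                 displacement_sd = displacement_sd,
                 stratum_rates = stratum_rates,
                 population_range = population_range,
                 population_gradient = population_gradient,
                 population_pattern = population_pattern,
                 low_pop_fraction = low_pop_fraction,
                 low_pop_floor = as.integer(low_pop_floor),
                 alpha_true = alpha_true, beta_true = beta_true,
                 nu_s_true = nu_s_true, nu_u_true = nu_u_true,
                 weight_scheme_true = weight_scheme_true,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Default age-sex stratum rates
#'
#' Event rates per person over the study window for 2 sexes x 5 senior age
#' groups, increasing five-fold from the youngest to the oldest group.
#'
#' @return named numeric vector of 10 rates.
#' @export
default_stratum_rates <- function() {
  ages <- c("65-69", "70-74", "75-79", "80-84", "85+")
  c(setNames(c(0.030, 0.050, 0.080, 0.115, 0.150), paste0("F:", ages)),
    setNames(c(0.024, 0.040, 0.064, 0.092, 0.120), paste0("M:", ages)))
}

scenario_seeds <- function(scenario) {
  derive_seeds(scenario$seed, c("map", "population", "covariates",
                                "icar", "unstructured", "counts"))
}

#' Generate an irregular lattice map with controlled vertex discrepancies
#'
#' Builds an `n_rows x n_cols` grid of quadrilateral areas, displaces every
#' lattice vertex by a clamped Normal offset so areas are irregular (the
#' displaced position is shared consistently by all incident polygons, so
#' true adjacency is preserved), then -- when `jitter_fraction > 0` --
#' picks that fraction of shared vertices and stores, in each incident
#' polygon's ring, an independently perturbed copy of the vertex
#' (`Normal(0, vertex_jitter_sd)` per coordinate). Exact-coordinate vertex
#' matching then misses adjacencies that depend on the duplicated vertices,
#' reproducing the behaviour of digitised maps in which the same boundary
#' point is recorded with close but different coordinates.
#'
#' @param scenario a [synthetic_scenario()].
#' @return object of class `synthetic_map`: list with `map` (an
#'   [area_map()]), `true_adjacency` (pre-jitter queen [adjacency_list()]),
#'   and `jitter` (picked vertex count and `magnitude`, the largest distance
#'   between duplicate copies of any picked vertex; a matching tolerance at
#'   least this large recovers the true adjacency).
#' @export
generate_lattice_map <- function(scenario) {
  nr <- scenario$n_rows; nc <- scenario$n_cols
  set.seed(scenario_seeds(scenario)[["map"]])

  # displaced lattice vertex positions, shared by all incident cells
  vid <- function(r, c) r * (nc + 1L) + c + 1L   # r in 0..nr, c in 0..nc
  n_vert <- (nr + 1L) * (nc + 1L)
  base <- cbind(x = rep(0:nc, times = nr + 1L), y = rep(0:nr, each = nc + 1L))
  disp <- matrix(rnorm(2L * n_vert, 0, scenario$displacement_sd), ncol = 2)
  disp <- pmin(pmax(disp, -0.3), 0.3)
  pos <- base + disp

  # ring vertex ids per cell, row-major cell order
  cells <- vector("list", nr * nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ids <- c(vid(i - 1L, j - 1L), vid(i - 1L, j), vid(i, j), vid(i, j - 1L))
    cells[[(i - 1L) * nc + j]] <- ids
  }
  incident <- vector("list", n_vert)
  for (k in seq_along(cells)) for (v in cells[[k]])
    incident[[v]] <- c(incident[[v]], k)

  # duplicate a fraction of shared vertices with perturbed per-cell copies
  shared <- which(vapply(incident, length, integer(1)) >= 2L)
  n_pick <- round(scenario$jitter_fraction * length(shared))
  picked <- if (n_pick > 0) sort(sample(shared, n_pick)) else integer(0)
  override <- list()  # override[[cell]][[as.character(vid)]] = coords
  magnitude <- 0
  for (v in picked) {
    copies <- NULL
    for (k in incident[[v]]) {
      pc <- pos[v, ] + rnorm(2, 0, scenario$vertex_jitter_sd)
      key <- as.character(k)
      if (is.null(override[[key]])) override[[key]] <- list()
      override[[key]][[as.character(v)]] <- pc
      copies <- rbind(copies, pc)
    }
    if (nrow(copies) >= 2) magnitude <- max(magnitude, max(dist(copies)))
  }

  polys <- lapply(seq_along(cells), function(k) {
    ids <- cells[[k]]
    coords <- pos[ids, , drop = FALSE]
    ov <- override[[as.character(k)]]
    if (!is.null(ov))
      for (vkey in names(ov)) coords[ids == as.integer(vkey), ] <-
        matrix(ov[[vkey]], sum(ids == as.integer(vkey)), 2, byrow = TRUE)
    rbind(coords, coords[1, , drop = FALSE])
  })
  ids <- sprintf("A%03d", seq_along(cells))
  map <- area_map(ids, polys)

  # ground-truth queen adjacency of the unjittered lattice
  nb <- vector("list", nr * nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    k <- (i - 1L) * nc + j
    js <- expand.grid(di = -1:1, dj = -1:1)
    js <- js[!(js$di == 0 & js$dj == 0), ]
    ii <- i + js$di; jj <- j + js$dj
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    nb[[k]] <- (ii[ok] - 1L) * nc + jj[ok]
  }
  truth <- adjacency_list(nb, ids)

  structure(list(map = map, true_adjacency = truth,
                 jitter = list(n_shared = length(shared), n_picked = n_pick,
                               picked = picked, magnitude = magnitude)),
            class = "synthetic_map")
}

#' Generate a stratified senior population
#'
#' Draws `N_ik` uniformly within an area-specific subrange of
#' `population_range` for each area and each of the 10 age-sex strata (with
#' `population_gradient > 0` the subrange upper end follows a smooth
#' diagonal surface across the map, so senior population is spatially
#' structured; at 0 the full range is used everywhere), then forces
#' `low_pop_fraction` of the areas to near-zero totals (total seniors
#' strictly below `low_pop_floor`, distributed multinomially over strata),
#' emulating study regions where some areas have almost no
#' population-at-risk. Case counts `Y` are zero; they are filled by the
#' outcome simulation.
#'
#' @param map a `synthetic_map` or [area_map()].
#' @param scenario a [synthetic_scenario()].
#' @return a [stratum_table()].
#' @export
generate_population <- function(map, scenario) {
  if (inherits(map, "synthetic_map")) map <- map$map
  set.seed(scenario_seeds(scenario)[["population"]])
  n <- length(map$area_ids)
  strata <- names(scenario$stratum_rates)
  K <- length(strata)
  rng <- scenario$population_range
  # spatial surface in [0, 1] modulating the subrange upper end
  s <- if (scenario$population_pattern == "patchy") {
    (runif(n) < 0.5) + 0
  } else {
    cx <- vapply(seq_len(n), function(i) mean(map_vertices(map, i)[, 1]), numeric(1))
    cy <- vapply(seq_len(n), function(i) mean(map_vertices(map, i)[, 2]), numeric(1))
    d <- (cx + cy) - min(cx + cy)
    if (max(d) > 0) d / max(d) else d
  }
  g <- (1 - scenario$population_gradient) + scenario$population_gradient * s
  hi <- rng[1] + round((rng[2] - rng[1]) * g)
  N <- matrix(0L, n, K)
  for (i in seq_len(n))   # guard the length-1 case: sample(x) != sample from {x}
    N[i, ] <- if (hi[i] == rng[1]) rep(rng[1], K)
              else sample(rng[1]:hi[i], K, replace = TRUE)
  n_low <- round(scenario$low_pop_fraction * n)
  if (n_low > 0) {
    low <- sample.int(n, n_low)
    for (i in low) {
      total <- sample(0:(scenario$low_pop_floor - 1L), 1)
      N[i, ] <- drop(rmultinom(1, total, rep(1, K)))
    }
  }
  parts <- strsplit(strata, ":", fixed = TRUE)
  stratum_table(data.frame(
    area_id = rep(map$area_ids, each = K),
    sex = rep(vapply(parts, `[`, "", 1), n),
    age_group = rep(vapply(parts, `[`, "", 2), n),
    N = as.integer(t(N)),
    Y = 0L), area_order = map$area_ids)
}

#' Simulate from the intrinsic CAR distribution
#'
#' Draws from the improper Gaussian with joint density proportional to
#' `exp(-(1/(2 variance)) * sum_{i<j} w_ij (S_i - S_j)^2)` restricted to the
#' sum-to-zero subspace, via the eigendecomposition of the weighted graph
#' Laplacian `Q` (`diag(w_plus) - W`): the constrained covariance is
#' `variance * pinv(Q)`.
#'
#' @param adj an [adjacency_list()]; must be connected.
#' @param weights a [weight_spec()] over `adj`.
#' @param variance the ICAR variance parameter (positive).
#' @param seed optional integer seed.
#' @param n_draws number of independent draws.
#' @return a length-`n` vector summing to zero, or an `n_draws x n` matrix.
#' @export
simulate_icar <- function(adj, weights, variance, seed = NULL, n_draws = 1) {
  if (!adjacency_connected(adj))
    stop_data("adjacency graph is disconnected; ICAR simulation requires one component")
  if (variance <= 0) stop_config("variance must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- adj$n
  Q <- matrix(0, n, n)
  pr <- weights$pairs
  Q[pr] <- -weights$w
  Q[pr[, 2:1, drop = FALSE]] <- -weights$w
  diag(Q) <- weights$w_plus
  eg <- eigen(Q, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  V <- eg$vectors[, keep, drop = FALSE]
  lam <- eg$values[keep]
  Z <- matrix(rnorm(n_draws * length(lam)), n_draws)
  S <- Z %*% (t(V) * sqrt(variance / lam))
  S <- S - rowMeans(S)  # exact sum-to-zero
  if (n_draws == 1) drop(S) else S
}

#' Simulate Poisson case counts
#'
#' `Y_i ~ Poisson(E_i * exp(alpha + x_i'beta + S_i + U_i))`; areas with
#' `E_i = 0` deterministically produce `Y_i = 0`.
#'
#' @param E nonnegative expected counts.
#' @param X covariate matrix (or `NULL`).
#' @param alpha intercept; `beta` coefficient vector.
#' @param S,U random-effect vectors (recycled scalars allowed).
#' @param seed optional integer seed.
#' @return integer vector of counts.
#' @export
simulate_counts <- function(E, X = NULL, alpha = 0, beta = NULL,
                            S = 0, U = 0, seed = NULL) {
  if (any(E < 0)) stop_data("expected counts must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(E)
  xb <- if (is.null(X) || length(beta) == 0) 0 else drop(as.matrix(X) %*% beta)
  lambda <- E * exp(alpha + xb + rep_len(S, n) + rep_len(U, n))
  rpois(n, lambda)
}

# spatially structured standardized covariates from area centroids
generate_covariates <- function(map, scenario) {
  if (inherits(map, "synthetic_map")) map <- map$map
  set.seed(scenario_seeds(scenario)[["covariates"]])
  n <- length(map$area_ids)
  cx <- vapply(seq_len(n), function(i) mean(map_vertices(map, i)[, 1]), numeric(1))
  cy <- vapply(seq_len(n), function(i) mean(map_vertices(map, i)[, 2]), numeric(1))
  q <- length(scenario$beta_true)
  std <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  X <- vapply(seq_len(q), function(k) {
    ang <- pi * (k - 1) / max(q, 1) / 2
    std(std(cos(ang) * cx + sin(ang) * cy) + rnorm(n, 0, 0.7))
  }, numeric(n))
  colnames(X) <- paste0("x", seq_len(q))
  X
}

#' Generate a complete synthetic small-area dataset
#'
#' Runs the whole generative pipeline of a scenario: map with ground-truth
#' adjacency, stratified population, covariates, true weights under the
#' scenario's scheme, spatial and unstructured random effects, and
#' stratum-level Poisson case counts `Y_ik ~ Poisson(N_ik z_k r_i)` (whose
#' area totals are the model's `Poisson(E_i r_i)` counts). Each stage uses
#' its own stream derived from the master seed, recorded in the output.
#'
#' @param scenario a [synthetic_scenario()].
#' @return object of class `synthetic_dataset`: `scenario`, `map` (a
#'   [generate_lattice_map()] result), `table` (a [stratum_table()] with
#'   simulated `Y`), `X`, `weights_true`, and `truth` (all generating
#'   parameters plus `E_true` and `r_true`).
#' @export
simulate_scenario <- function(scenario) {
  seeds <- scenario_seeds(scenario)
  smap <- generate_lattice_map(scenario)
  table <- generate_population(smap, scenario)
  X <- generate_covariates(smap, scenario)
  n <- length(smap$map$area_ids)

  N <- stratum_matrix(table, "N")
  z <- scenario$stratum_rates[colnames(N)]
  E_true <- drop(N %*% z)
  totals <- rowSums(N)

  # Generator value vectors are scaled to mean 1 (floored at 0.01) so that
  # nu_s_true governs the field's actual scale: product weights are only
  # defined up to a constant (nu_s absorbs rescaling at fit time), but in
  # generation nu_s is fixed, so an unscaled vector would silently change
  # the amount of spatial structure. The floor keeps near-empty areas from
  # getting near-infinite conditional variances.
  scale_values <- function(v) pmax(v / mean(v), 0.01)
  weights_true <- switch(scenario$weight_scheme_true,
    equal = equal_weights(smap$true_adjacency),
    population = product_weights(smap$true_adjacency, scale_values(totals),
                                 scheme_label = "population"),
    density = product_weights(smap$true_adjacency,
                              scale_values(totals / polygon_area(smap$map)),
                              scheme_label = "density"),
    expected = product_weights(smap$true_adjacency, scale_values(E_true),
                               scheme_label = "expected"))

  S <- simulate_icar(smap$true_adjacency, weights_true, scenario$nu_s_true,
                     seed = seeds[["icar"]])
  set.seed(seeds[["unstructured"]])
  U <- rnorm(n, 0, sqrt(scenario$nu_u_true))
  r <- exp(scenario$alpha_true + drop(X %*% scenario$beta_true) + S + U)

  set.seed(seeds[["counts"]])
  Yik <- matrix(rpois(length(N), t(N) * z * rep(r, each = ncol(N))),
                nrow = ncol(N))  # strata x areas, matching table row order
  table$Y <- as.integer(Yik)

  structure(list(scenario = scenario, map = smap, table = table, X = X,
                 weights_true = weights_true,
                 truth = list(alpha = scenario$alpha_true,
                              beta = scenario$beta_true,
                              S = S, U = U,
                              nu_s = scenario$nu_s_true,
                              nu_u = scenario$nu_u_true,
                              z = z, E_true = E_true, r_true = r),
                 seeds = as.list(seeds)),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes the GeoJSON map, the stratum table and covariates as CSV, the
#' true adjacency as a WinBUGS file, and all ground-truth parameters plus
#' scenario and seeds as JSON.
#'
#' @param data a [simulate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(scenario = unclass(data$scenario), seeds = data$seeds)
  write_area_map_geojson(data$map$map, file.path(dir, "map.geojson"),
                         metadata = meta)
  write.csv(as.data.frame(data$table), file.path(dir, "strata.csv"),
            row.names = FALSE)
  write.csv(data.frame(area_id = data$map$map$area_ids, data$X),
            file.path(dir, "covariates.csv"), row.names = FALSE)
  write_winbugs_adjacency(data$map$true_adjacency, data$weights_true,
                          file.path(dir, "adjacency_true.txt"))
  jsonlite::write_json(c(meta, list(truth = data$truth)),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
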