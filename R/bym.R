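#' Full conditional of the ICAR prior
#'
#' The defining conditional of the intrinsic CAR model with symmetric
#' weights: given its neighbours, `S_i` is Normal with mean the weighted
#' average `sum_j w_ij S_j / w_i+` and variance `nu_s / w_i+`.
#'
#' @param i area index (1-based).
#' @param S current vector of spatial effects.
#' @param ws a [weight_spec()].
#' @param nu_s the ICAR variance parameter.
#' @return list with `mean` and `variance`.
#' @export
icar_conditional <- function(i, S, ws, nu_s) {
  wp <- ws$w_plus[i]
  if (wp <= 0) stop_data("area %s has no neighbors (w_plus = 0)",
                         ws$adjacency$area_ids[i])
  js <- ws$adjacency$neighbors[[i]]
  wj <- aligned_weights(ws)[[i]]
  list(mean = sum(wj * S[js]) / wp, variance = nu_s / wp)
}

#' Specify a Poisson BYM convolution model
#'
#' Validates data and priors for the hierarchical model
#' `Y_i ~ Poisson(lambda_i)`,
#' `log lambda_i = log E_i + alpha + x_i'beta + S_i + U_i`, with `U_i ~
#' Normal(0, nu_u)`, `S` an intrinsic CAR field under the supplied weights
#' (spatial dependence parameter fixed at its maximum of 1), a flat prior on
#' `alpha`, independent `Normal(0, prior_beta_var)` priors on the
#' coefficients, and a common `Gamma(shape, rate)` prior on both precisions
#' `1/nu_u` and `1/nu_s`.
#'
#' Areas with `E_i = 0` (possible under indirect standardization when an
#' area has no population-at-risk) are floored at `e_floor` with a warning
#' naming them, so the log-offset stays finite. Island areas (no
#' neighbours) and disconnected maps are rejected: the ICAR rank correction
#' used by the precision update assumes one connected component.
#'
#' @param Y nonnegative integer case counts.
#' @param E expected counts (offset), length `n`.
#' @param weights a [weight_spec()].
#' @param X optional covariate matrix (`n x q`).
#' @param prior_beta_var variance of the Normal prior on each coefficient
#'   (default 10000, i.e. sd 100).
#' @param prior_precision `c(shape, rate)` of the Gamma hyperprior on the
#'   precisions; default `c(0.5, 0.0005)` (see [implied_sd_prior()]),
#'   alternative `c(0.001, 0.001)` for sensitivity analysis.
#' @param e_floor positive replacement for zero expected counts.
#' @return object of class `bym_model`.
#' @export
bym_model <- function(Y, E, weights, X = NULL,
                      prior_beta_var = 1e4,
                      prior_precision = c(shape = 0.5, rate = 5e-4),
                      e_floor = 1e-4) {
  adj <- weights$adjacency
  n <- adj$n
  if (n < 2) stop_data("ICAR model undefined for a single area")
  if (length(Y) != n || length(E) != n) stop_data("Y, E and adjacency lengths differ")
  if (any(Y < 0)) stop_data("negative case counts")
  if (any(Y != round(Y))) stop_data("case counts must be integers")
  if (any(E < 0)) stop_data("negative expected counts")
  islands <- which(adj$num == 0L)
  if (length(islands))
    stop_data("island area(s) with no neighbors: %s",
              paste(adj$area_ids[islands], collapse = ", "))
  if (!adjacency_connected(adj))
    stop_data("adjacency graph is disconnected; fit components separately")
  if (e_floor <= 0) stop_config("e_floor must be positive")
  if (any(prior_precision <= 0) || length(prior_precision) != 2)
    stop_config("prior_precision must be positive c(shape, rate)")
  zero_e <- which(E == 0)
  if (length(zero_e)) {
    warning(sprintf("zero expected count floored at %g in area(s): %s",
                    e_floor, paste(adj$area_ids[zero_e], collapse = ", ")))
    E[zero_e] <- e_floor
  }
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  if (nrow(X) != n) stop_data("covariate matrix must have %d rows", n)
  structure(list(Y = as.integer(Y), E = as.numeric(E), X = X,
                 weights = weights,
                 prior_beta_var = prior_beta_var,
                 prior_precision = setNames(as.numeric(prior_precision),
                                            c("shape", "rate")),
                 rho = 1, e_floor = e_floor, zero_e = zero_e),
            class = "bym_model")
}

#' @export
print.bym_model <- function(x, ...) {
  cat(sprintf("bym_model: %d areas, %d covariate(s), %s weights, Gamma(%g, %g) hyperprior\n",
              length(x$Y), ncol(x$X), x$weights$scheme_label,
              x$prior_precision[["shape"]], x$prior_precision[["rate"]]))
  invisible(x)
}

#' Sampler configuration
#'
#' Defaults follow the reference analysis protocol: 2 chains, convergence
#' by 20,000 burn-in iterations, then a further 10,000 retained per chain
#' giving 20,000 posterior samples (thin 1).
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param burn_in discarded iterations per chain (adaptation happens here).
#' @param keep retained iterations per chain.
#' @param thin retention stride.
#' @param seed master seed; per-chain streams are derived from it.
#' @param adapt_window sweeps between step-size adaptations during burn-in.
#' @param target_acceptance target acceptance rate of the scalar
#'   random-walk updates (0.44, the scalar optimum).
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 2, burn_in = 20000, keep = 10000,
                           thin = 1, seed = 1L, adapt_window = 50,
                           target_acceptance = 0.44) {
  if (any(c(n_chains, burn_in, keep, thin, adapt_window) < 1))
    stop_config("sampler settings must be positive")
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 keep = as.integer(keep), thin = as.integer(thin),
                 seed = as.integer(seed), adapt_window = as.integer(adapt_window),
                 target_acceptance = target_acceptance),
            class = "sampler_config")
}

#' Fit a BYM model by Metropolis-within-Gibbs MCMC
#'
#' Each sweep updates every `S_i` by scalar random-walk Metropolis against
#' the Poisson likelihood times the ICAR pairwise-difference prior, then
#' recentres `S` to sum to zero (the shift absorbed into `alpha`, valid
#' under its flat prior); updates every `U_i`, then `alpha` and each
#' coefficient, by scalar random-walk Metropolis; and draws the two
#' precisions from their conjugate Gamma full conditionals
#' (`1/nu_u ~ Gamma(a + n/2, b + sum U^2 / 2)`,
#' `1/nu_s ~ Gamma(a + (n-1)/2, b + sum_{i<j} w_ij (S_i - S_j)^2 / 2)`).
#' Step sizes adapt toward the target acceptance rate during burn-in only.
#' A fixed seed yields bit-identical chains.
#'
#' @param model a [bym_model()].
#' @param config a [sampler_config()].
#' @return object of class `bym_fit`: per-chain draws of `alpha`, `beta`,
#'   `S`, `U`, `nu_s`, `nu_u`, plus the model and configuration.
#' @export
run_mcmc <- function(model, config = sampler_config()) {
  if (!inherits(model, "bym_model")) stop_data("model must be a bym_model")
  adj <- model$weights$adjacency
  aw <- aligned_weights(model$weights)
  nbr0 <- lapply(adj$neighbors, function(v) v - 1L)
  pr <- model$weights$pairs
  init_alpha <- log(sum(model$Y) / sum(model$E))
  chain_seeds <- derive_seeds(config$seed, paste0("chain", seq_len(config$n_chains)))
  chains <- vector("list", config$n_chains)
  for (cc in seq_len(config$n_chains)) {
    set.seed(chain_seeds[cc])
    chains[[cc]] <- bym_mcmc_chain(
      model$Y, model$E, model$X,
      nbr0, aw, model$weights$w_plus,
      pr[, 1] - 1L, pr[, 2] - 1L, model$weights$w,
      model$prior_beta_var,
      model$prior_precision[["shape"]], model$prior_precision[["rate"]],
      config$burn_in, config$keep, config$thin,
      config$adapt_window, config$target_acceptance,
      init_alpha)
    colnames(chains[[cc]]$beta) <- colnames(model$X)
  }
  structure(list(chains = chains, model = model, config = config,
                 chain_seeds = unname(chain_seeds)),
            class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat(sprintf("bym_fit: %d chain(s) x %d retained draws, %d areas, %s weights\n",
              length(x$chains), length(x$chains[[1]]$alpha),
              length(x$model$Y), x$model$weights$scheme_label))
  invisible(x)
}

# draws of one quantity pooled over chains (rows = iterations)
combine_draws <- function(fit, what) {
  do.call(rbind, lapply(fit$chains, function(ch) {
    d <- ch[[what]]
    if (is.matrix(d)) d else matrix(d, ncol = 1)
  }))
}

#' Per-iteration relative-risk draws
#'
#' `r_i = exp(alpha + x_i'beta + S_i + U_i)` for every retained iteration,
#' pooled over chains.
#'
#' @param fit a [run_mcmc()] fit.
#' @return matrix (total retained iterations x areas).
#' @export
risk_draws <- function(fit) {
  X <- fit$model$X
  do.call(rbind, lapply(fit$chains, function(ch) {
    eta <- ch$S + ch$U + ch$alpha
    if (ncol(X) > 0) eta <- eta + ch$beta %*% t(X)
    exp(eta)
  }))
}

#' Prior on the random-effect standard deviation implied by a Gamma
#' precision hyperprior
#'
#' For precision `tau ~ Gamma(shape, rate)` and `sd = tau^(-1/2)`, returns
#' where the prior centres the standard deviation and how much mass it puts
#' in the extreme tails, all through the Gamma distribution function (no
#' sampling). The default hyperprior Gamma(0.5, 0.0005) centres the sd near
#' 0.05 with about 1% total probability of sd below 0.01 or above 2.5.
#'
#' @param shape,rate positive Gamma parameters (rate parameterisation).
#' @param sd_low,sd_high tail cutpoints on the sd scale.
#' @return list with `median_sd`, `p_below` (`P(sd < sd_low)`), `p_above`
#'   (`P(sd > sd_high)`).
#' @export
implied_sd_prior <- function(shape, rate, sd_low = 0.01, sd_high = 2.5) {
  if (shape <= 0 || rate <= 0) stop_config("shape and rate must be positive")
  median_tau <- qgamma(0.5, shape = shape, rate = rate)
  list(median_sd = median_tau^(-0.5),
       p_below = pgamma(sd_low^(-2), shape = shape, rate = rate,
                        lower.tail = FALSE),
       p_above = pgamma(sd_high^(-2), shape = shape, rate = rate))
}

#' Export retained draws as CSV with a JSON metadata sidecar
#'
#' One row per retained iteration (chain and iteration indices included),
#' scalar parameters and every `S_i`/`U_i` as columns; the sidecar records
#' seed, configuration, priors and weight scheme.
#'
#' @param fit a [run_mcmc()] fit.
#' @param path output CSV; the sidecar is `<path>.meta.json`.
#' @return `path`, invisibly.
#' @export
write_chains <- function(fit, path) {
  tabs <- lapply(seq_along(fit$chains), function(cc) {
    ch <- fit$chains[[cc]]
    q <- ncol(ch$beta)
    df <- data.frame(chain = cc, iteration = seq_along(ch$alpha),
                     alpha = ch$alpha)
    if (q > 0) {
      b <- as.data.frame(ch$beta)
      names(b) <- paste0("beta_", if (is.null(colnames(ch$beta)))
        seq_len(q) else colnames(ch$beta))
      df <- cbind(df, b)
    }
    df$nu_s <- ch$nu_s; df$nu_u <- ch$nu_u
    S <- as.data.frame(ch$S); names(S) <- paste0("S_", seq_len(ncol(ch$S)))
    U <- as.data.frame(ch$U); names(U) <- paste0("U_", seq_len(ncol(ch$U)))
    cbind(df, S, U)
  })
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  meta <- list(seed = fit$config$seed, config = unclass(fit$config),
               prior_precision = as.list(fit$model$prior_precision),
               prior_beta_var = fit$model$prior_beta_var,
               scheme_label = fit$model$weights$scheme_label,
               chain_seeds = fit$chain_seeds)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
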