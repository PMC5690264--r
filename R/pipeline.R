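#' Univariate covariate screening
#'
#' Fits the convolution model with one covariate at a time under equal
#' weights (screening is always done under equal weights, whatever scheme
#' is later compared) and selects the covariates whose equal-tailed
#' credible interval at `level` excludes zero. Constant covariates are
#' excluded with a warning.
#'
#' @param Y,E counts and expected counts.
#' @param X covariate matrix with at least one column.
#' @param adj an [adjacency_list()].
#' @param sampler a [sampler_config()].
#' @param level credible level (default 0.95).
#' @param ... passed to [bym_model()] (priors, `e_floor`).
#' @return list with `selected` (column names) and `table` (one row per
#'   covariate: posterior mean, CI bounds, selected flag).
#' @export
univariate_screen <- function(Y, E, X, adj, sampler = sampler_config(),
                              level = 0.95, ...) {
  X <- as.matrix(X)
  if (ncol(X) < 1)
    return(list(selected = character(0),
                table = data.frame(covariate = character(0),
                                   estimate = numeric(0), lower = numeric(0),
                                   upper = numeric(0), selected = logical(0))))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ws <- equal_weights(adj)
  a <- (1 - level) / 2
  rows <- lapply(colnames(X), function(nm) {
    x <- X[, nm]
    if (sd(x) == 0) {
      warning(sprintf("constant covariate '%s' excluded from screening", nm))
      return(data.frame(covariate = nm, estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, selected = FALSE))
    }
    fit <- run_mcmc(bym_model(Y, E, ws, X = X[, nm, drop = FALSE], ...), sampler)
    b <- combine_draws(fit, "beta")[, 1]
    ci <- unname(quantile(b, c(a, 1 - a)))
    data.frame(covariate = nm, estimate = mean(b), lower = ci[1], upper = ci[2],
               selected = ci[1] > 0 | ci[2] < 0)
  })
  table <- do.call(rbind, rows)
  list(selected = table$covariate[table$selected], table = table)
}

#' Percentile category indicators
#'
#' Re-expresses a continuous area-level variable as category dummies at the
#' given percentile cutpoints (default quartiles: indicators for the
#' categories above the 25th, 50th and 75th percentiles, the bottom
#' category being the reference). Percentiles use the nearest-rank method;
#' a value tied with a cutpoint falls in the lower category.
#'
#' @param x per-area values with at least 4 distinct values.
#' @param cutpoints strictly increasing percentages in (0, 100).
#' @return integer indicator matrix with one column per cutpoint (for the
#'   default cutpoints: membership of Q2, Q3, Q4 versus the Q1 reference).
#' @export
percentile_dummies <- function(x, cutpoints = c(25, 50, 75)) {
  if (length(unique(x)) < 4) stop_data("need at least 4 distinct values")
  if (any(cutpoints <= 0 | cutpoints >= 100) || is.unsorted(cutpoints, strictly = TRUE))
    stop_config("cutpoints must be strictly increasing in (0, 100)")
  n <- length(x)
  xs <- sort(x)
  p <- xs[ceiling(cutpoints / 100 * n)]  # nearest-rank percentiles
  cat_idx <- rowSums(outer(x, p, ">"))   # 0 = reference category
  m <- outer(cat_idx, seq_along(p), "==") + 0L
  colnames(m) <- paste0("gt_p", cutpoints)
  m
}

#' Compare spatial weight schemes on identical data
#'
#' Fits the same model (same `Y`, `E`, `X`, adjacency, priors, seed and
#' sampler configuration) once per weight scheme and compares fits by DIC.
#' A winner is flagged only when its DIC undercuts every other converged
#' scheme by more than `margin`; schemes failing the convergence gate
#' (`rhat > 1.1` or MC-error ratio >= 5%) are flagged and excluded from the
#' winner decision.
#'
#' @param Y,E counts and expected counts.
#' @param X covariate matrix or `NULL`.
#' @param adj an [adjacency_list()].
#' @param schemes character subset of `c("equal", "population", "density",
#'   "expected")` (>= 2 of them).
#' @param values named list supplying the per-area variable for each
#'   product scheme requested (`population`, `density`, `expected`);
#'   `expected` defaults to `E`.
#' @param sampler a [sampler_config()].
#' @param margin DIC decision margin (default 5).
#' @param keep_fits return the full fits (memory permitting).
#' @param ... passed to [bym_model()].
#' @return list with `dic_table`, `winner` (scheme label or `NA`),
#'   `summaries` (per scheme: coefficient table, spatial fraction, risk
#'   summaries, exceedance counts, diagnostics), and optionally `fits`.
#' @export
compare_weight_schemes <- function(Y, E, X, adj,
                                   schemes = c("equal", "population",
                                               "density", "expected"),
                                   values = list(),
                                   sampler = sampler_config(),
                                   margin = 5, keep_fits = FALSE, ...) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  if (length(schemes) < 2) stop_config("need at least 2 schemes to compare")
  if (margin <= 0) stop_config("margin must be positive")
  if (is.null(values$expected)) values$expected <- E
  # Pair weights are defined only up to a constant (the ICAR variance
  # absorbs rescaling), so value vectors are normalised to mean 1 and
  # floored at 1% of the mean: near-empty areas stay weakly coupled to
  # their neighbours instead of effectively detaching, which would leave
  # their spatial effects unidentified and destabilise the deviance.
  make_ws <- function(s) {
    if (s == "equal") return(equal_weights(adj))
    v <- values[[s]]
    if (is.null(v)) stop_config("no value vector supplied for scheme '%s'", s)
    if (any(v < 0) || mean(v) <= 0) stop_data("scheme '%s' values must be nonnegative", s)
    product_weights(adj, pmax(v / mean(v), 0.01), scheme_label = s)
  }
  fits <- list(); summaries <- list(); rows <- list()
  for (s in schemes) {
    fit <- run_mcmc(bym_model(Y, E, make_ws(s), X = X, ...), sampler)
    dg <- diagnostics_report(fit)
    beta <- if (ncol(fit$model$X) > 0) {
      b <- combine_draws(fit, "beta")
      data.frame(covariate = colnames(fit$model$X),
                 estimate = colMeans(b),
                 lower = apply(b, 2, quantile, 0.025),
                 upper = apply(b, 2, quantile, 0.975),
                 row.names = NULL)
    } else data.frame()
    summaries[[s]] <- list(coefficients = beta,
                           spatial_fraction = dg$spatial_fraction,
                           pD = dg$pD, DIC = dg$DIC,
                           risks = summarize_risks(fit),
                           exceedance = exceedance_probabilities(fit),
                           diagnostics = dg)
    rows[[s]] <- data.frame(scheme = s, Dbar = dg$Dbar, pD = dg$pD,
                            DIC = dg$DIC, converged = dg$converged)
    if (keep_fits) fits[[s]] <- fit
  }
  dic_table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  ok <- dic_table[dic_table$converged, ]
  winner <- NA_character_
  if (nrow(ok) >= 2) {
    ord <- ok[order(ok$DIC), ]
    if (ord$DIC[2] - ord$DIC[1] > margin) winner <- ord$scheme[1]
  }
  out <- list(dic_table = dic_table, winner = winner, summaries = summaries)
  if (keep_fits) out$fits <- fits
  out
}

#' Analysis configuration
#'
#' Bundles every knob of the end-to-end workflow. Data can be given as file
#' paths (GeoJSON map, stratum CSV, covariate CSV) or as in-memory objects;
#' alternatively a [synthetic_scenario()] generates everything.
#'
#' @param map,strata,covariates paths or objects ([area_map()],
#'   [stratum_table()], covariate matrix with `area_id`-ordered rows).
#' @param scenario optional [synthetic_scenario()] used instead of files.
#' @param reference_adjacency optional true [adjacency_list()] (or WinBUGS
#'   file path) to audit the extracted adjacency against.
#' @param tolerance vertex-matching tolerance for adjacency extraction.
#' @param schemes weight schemes to compare.
#' @param screening_level credible level of the univariate screen.
#' @param percentile_covariates character vector of covariate names to
#'   re-express as percentile category dummies in the final model.
#' @param cutpoints percentile cutpoints for those dummies.
#' @param sampler a [sampler_config()].
#' @param prior_precision,sensitivity_prior primary and sensitivity Gamma
#'   hyperpriors `c(shape, rate)` on the random-effect precisions.
#' @param dic_margin DIC decision margin.
#' @param out_dir output directory (`NULL` for no files).
#' @param seed master seed.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(map = NULL, strata = NULL, covariates = NULL,
                            scenario = NULL, reference_adjacency = NULL,
                            tolerance = 0,
                            schemes = c("equal", "population", "density",
                                        "expected"),
                            screening_level = 0.95,
                            percentile_covariates = character(0),
                            cutpoints = c(25, 50, 75),
                            sampler = sampler_config(),
                            prior_precision = c(shape = 0.5, rate = 5e-4),
                            sensitivity_prior = c(shape = 0.001, rate = 0.001),
                            dic_margin = 5, out_dir = NULL, seed = 1L) {
  if (any(cutpoints <= 0 | cutpoints >= 100) ||
      is.unsorted(cutpoints, strictly = TRUE))
    stop_config("cutpoints must be strictly increasing in (0, 100)")
  if (dic_margin <= 0) stop_config("dic_margin must be positive")
  if (is.null(scenario) && (is.null(map) || is.null(strata)))
    stop_config("supply either a scenario or map + strata inputs")
  structure(list(map = map, strata = strata, covariates = covariates,
                 scenario = scenario,
                 reference_adjacency = reference_adjacency,
                 tolerance = tolerance, schemes = schemes,
                 screening_level = screening_level,
                 percentile_covariates = percentile_covariates,
                 cutpoints = cutpoints, sampler = sampler,
                 prior_precision = prior_precision,
                 sensitivity_prior = sensitivity_prior,
                 dic_margin = dic_margin, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

resolve_inputs <- function(config) {
  if (!is.null(config$scenario)) {
    data <- simulate_scenario(config$scenario)
    return(list(map = data$map$map, table = data$table, X = data$X,
                reference = data$map$true_adjacency, synthetic = data))
  }
  map <- if (is.character(config$map)) read_area_map_geojson(config$map) else config$map
  table <- if (is.character(config$strata))
    read_stratum_table(config$strata, area_order = map$area_ids) else config$strata
  X <- config$covariates
  if (is.character(X)) {
    df <- read.csv(X, colClasses = c(area_id = "character"))
    X <- as.matrix(df[match(map$area_ids, df$area_id),
                      setdiff(names(df), "area_id"), drop = FALSE])
  }
  reference <- config$reference_adjacency
  if (is.character(reference)) reference <- read_winbugs_adjacency(reference)$adjacency
  list(map = map, table = table, X = X, reference = reference, synthetic = NULL)
}

#' Run the full small-area analysis workflow
#'
#' End to end: adjacency extraction (plus a discrepancy audit when a
#' reference adjacency is available) -> indirect standardization ->
#' univariate covariate screening under equal weights -> final multivariate
#' model (screened covariates, with configured covariates re-expressed as
#' percentile dummies) fitted under every requested weight scheme with a
#' shared data path and seed -> DIC comparison, diagnostics and posterior
#' summaries -> sensitivity rerun of the winning comparison under the
#' alternative hyperprior. All artifacts are written to `out_dir` (when
#' set) together with run metadata including input hashes.
#'
#' @param config an [analysis_config()].
#' @return list with elements `adjacency`, `discrepancy`, `standardization`,
#'   `screening`, `final_covariates`, `comparison`, `sensitivity`,
#'   `metadata`.
#' @export
run_full_analysis <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(sprintf("[%s] %s", name, conditionMessage(e)),
                          class = class(e)))
    })
  }
  inputs <- stage("inputs", resolve_inputs(config))
  adj <- stage("adjacency", extract_queen_adjacency(inputs$map, config$tolerance))
  discrepancy <- if (!is.null(inputs$reference))
    stage("adjacency", compare_adjacency(inputs$reference, adj)) else NULL
  # model the true structure when auditing shows the extraction lost pairs
  model_adj <- if (!is.null(inputs$reference)) inputs$reference else adj

  std <- stage("standardization", {
    tot <- area_totals(inputs$table)
    E <- expected_counts(inputs$table)
    list(totals = tot, E = unname(E), sir = sir(tot$Y, E))
  })

  X <- inputs$X
  screening <- NULL
  final_X <- NULL
  if (!is.null(X) && ncol(X) > 0) {
    screening <- stage("screening",
      univariate_screen(std$totals$Y, std$E, X, model_adj,
                        sampler = config$sampler,
                        level = config$screening_level,
                        prior_precision = config$prior_precision))
    keep <- screening$selected
    cols <- list()
    for (nm in keep) {
      if (nm %in% config$percentile_covariates) {
        d <- percentile_dummies(X[, nm], config$cutpoints)
        colnames(d) <- paste0(nm, "_", colnames(d))
        cols[[nm]] <- d
      } else cols[[nm]] <- setNames(data.frame(X[, nm]), nm)
    }
    if (length(cols)) final_X <- as.matrix(do.call(cbind, unname(cols)))
  }

  comparison <- stage("comparison", compare_weight_schemes(
    std$totals$Y, std$E, final_X, model_adj,
    schemes = config$schemes,
    values = list(population = std$totals$N,
                  density = std$totals$N / polygon_area(inputs$map),
                  expected = std$E),
    sampler = config$sampler, margin = config$dic_margin,
    prior_precision = config$prior_precision))

  sensitivity <- stage("sensitivity", compare_weight_schemes(
    std$totals$Y, std$E, final_X, model_adj,
    schemes = config$schemes,
    values = list(population = std$totals$N,
                  density = std$totals$N / polygon_area(inputs$map),
                  expected = std$E),
    sampler = config$sampler, margin = config$dic_margin,
    prior_precision = config$sensitivity_prior))

  metadata <- list(
    seed = config$seed,
    tolerance = config$tolerance,
    schemes = config$schemes,
    hyperprior = as.list(setNames(config$prior_precision, c("shape", "rate"))),
    sensitivity_hyperprior = as.list(setNames(config$sensitivity_prior,
                                              c("shape", "rate"))),
    dic_margin = config$dic_margin,
    percentile_note = paste("percentile covariates entered as category",
                            "dummies at cutpoints",
                            paste(config$cutpoints, collapse = "/"),
                            "with the bottom category as reference"),
    input_hashes = list(Y = hash_object(std$totals$Y),
                        E = hash_object(std$E),
                        X = hash_object(final_X),
                        adjacency = hash_object(model_adj)),
    package_version = as.character(utils::packageVersion("bymweights")))

  out <- list(adjacency = adj, discrepancy = discrepancy,
              standardization = std, screening = screening,
              final_covariates = final_X, comparison = comparison,
              sensitivity = sensitivity, metadata = metadata)

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_winbugs_adjacency(adj, path = file.path(dir, "adjacency.txt"))
    if (!is.null(discrepancy))
      jsonlite::write_json(list(total_true = discrepancy$total_true,
                                total_generated = discrepancy$total_generated,
                                undercount_error = discrepancy$undercount_error,
                                n_missing = nrow(discrepancy$missing_pairs),
                                n_extra = nrow(discrepancy$extra_pairs)),
                           file.path(dir, "discrepancy.json"),
                           auto_unbox = TRUE, digits = NA)
    write_standardization(inputs$table, file.path(dir, "standardization.csv"))
    if (!is.null(screening))
      write.csv(screening$table, file.path(dir, "screening.csv"), row.names = FALSE)
    write.csv(comparison$dic_table, file.path(dir, "dic_table.csv"),
              row.names = FALSE)
    for (s in names(comparison$summaries)) {
      sm <- comparison$summaries[[s]]
      write.csv(cbind(area_id = model_adj$area_ids, sm$risks$per_area,
                      exceedance = sm$exceedance$prob),
                file.path(dir, sprintf("risks_%s.csv", s)), row.names = FALSE)
      write_diagnostics(sm$diagnostics,
                        file.path(dir, sprintf("diagnostics_%s.json", s)))
    }
    for (s in names(sensitivity$summaries))
      write_diagnostics(sensitivity$summaries[[s]]$diagnostics,
                        file.path(dir, sprintf("diagnostics_sensitivity_%s.json", s)))
    jsonlite::write_json(metadata, file.path(dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
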