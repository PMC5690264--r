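#' Construct a spatial weight specification
#'
#' Symmetric positive pair weights `w_ij` over the adjacent pairs of an
#' [adjacency_list()], together with the per-area totals
#' `w_i+ = sum_j w_ij` that scale the ICAR conditional variance. Weights are
#' stored unnormalised, which is the form the `car.normal`-style sampler
#' consumes; row-normalised weights are a derived, reporting-only view
#' ([normalized_rows()]).
#'
#' @param adjacency an [adjacency_list()].
#' @param w numeric vector of positive weights, one per unordered adjacent
#'   pair, aligned with `adjacency_pairs(adjacency)` (pairs sorted by i then
#'   j, i < j).
#' @param scheme_label one of `"equal"`, `"population"`, `"density"`,
#'   `"expected"`, `"custom"`.
#' @return object of class `weight_spec` with fields `adjacency`, `pairs`,
#'   `w`, `w_plus`, `scheme_label`.
#' @export
weight_spec <- function(adjacency, w,
                        scheme_label = c("custom", "equal", "population",
                                         "density", "expected")) {
  scheme_label <- match.arg(scheme_label)
  pairs <- adjacency_pairs(adjacency)
  w <- unname(as.numeric(w))
  if (length(w) != nrow(pairs))
    stop_data("need one weight per adjacent pair (%d), got %d", nrow(pairs), length(w))
  if (any(!is.finite(w)) || any(w <= 0))
    stop_data("weights must be positive and finite")
  w_plus <- numeric(adjacency$n)
  if (nrow(pairs)) {
    tab_i <- tapply(c(w, w), c(pairs[, 1], pairs[, 2]), sum)
    w_plus[as.integer(names(tab_i))] <- tab_i
  }
  structure(list(adjacency = adjacency, pairs = pairs, w = w,
                 w_plus = w_plus, scheme_label = scheme_label),
            class = "weight_spec")
}

#' @export
print.weight_spec <- function(x, ...) {
  cat(sprintf("weight_spec (%s): %d areas, %d pairs, w in [%g, %g]\n",
              x$scheme_label, x$adjacency$n, nrow(x$pairs),
              if (length(x$w)) min(x$w) else NA, if (length(x$w)) max(x$w) else NA))
  invisible(x)
}

# per-area neighbour weights aligned with adjacency$neighbors[[i]]
aligned_weights <- function(ws) {
  key <- setNames(ws$w, paste(ws$pairs[, 1], ws$pairs[, 2]))
  lapply(seq_len(ws$adjacency$n), function(i) {
    js <- ws$adjacency$neighbors[[i]]
    unname(key[paste(pmin(i, js), pmax(i, js))])
  })
}

# weights aligned with the flattened adj vector (WinBUGS order)
aligned_weights_flat <- function(ws) unlist(aligned_weights(ws))

#' Equal spatial weights
#'
#' The conventional binary specification: `w_ij = 1` for every adjacent
#' pair, so `w_i+` equals the neighbour count.
#'
#' @param adj an [adjacency_list()].
#' @return a [weight_spec()] with `scheme_label = "equal"`.
#' @export
equal_weights <- function(adj) {
  weight_spec(adj, rep(1, nrow(adjacency_pairs(adj))), scheme_label = "equal")
}

#' Variable product weights
#'
#' Weights each adjacent pair by the product of a per-area variable:
#' `w_ij = values_i * values_j`, floored below to keep every weight (and
#' hence every `w_i+`) strictly positive when some areas have a zero value.
#' With `values` equal to senior population counts, population densities, or
#' expected case counts this yields the three variable-weight schemes
#' compared against equal weights; with `values` identically 1 it reduces to
#' [equal_weights()].
#'
#' @param adj an [adjacency_list()].
#' @param values nonnegative per-area variable, length `adj$n`.
#' @param floor positive lower bound applied to each product; default
#'   `1e-6 *` the median positive raw product (absolute fallback `1e-6` when
#'   all products are zero). Floored pairs are reported in a message.
#' @param scheme_label label recorded on the result.
#' @return a [weight_spec()].
#' @export
product_weights <- function(adj, values, floor = NULL,
                            scheme_label = c("custom", "population",
                                             "density", "expected", "equal")) {
  scheme_label <- match.arg(scheme_label)
  values <- as.numeric(values)
  if (length(values) != adj$n)
    stop_data("need one value per area (%d), got %d", adj$n, length(values))
  if (any(!is.finite(values)) || any(values < 0))
    stop_data("values must be nonnegative and finite")
  pairs <- adjacency_pairs(adj)
  raw <- values[pairs[, 1]] * values[pairs[, 2]]
  if (is.null(floor)) {
    pos <- raw[raw > 0]
    floor <- if (length(pos)) 1e-6 * median(pos) else 1e-6
  }
  if (floor <= 0) stop_config("floor must be positive")
  n_floored <- sum(raw < floor)
  if (n_floored > 0)
    message(sprintf("product_weights: %d pair weight(s) below %g floored", n_floored, floor))
  weight_spec(adj, pmax(raw, floor), scheme_label = scheme_label)
}

#' Row-normalised weights
#'
#' The reporting view `w_ij / w_i+` in which each area's weights sum to 1,
#' i.e. the row-stochastic form of the adjacency matrix. The model itself
#' consumes the unnormalised weights and `w_i+`.
#'
#' @param ws a [weight_spec()].
#' @return list (one element per area) of normalised neighbour weights,
#'   aligned with `ws$adjacency$neighbors`; each element sums to 1.
#' @export
normalized_rows <- function(ws) {
  islands <- which(ws$w_plus == 0)
  if (length(islands))
    stop_data("cannot normalise rows: area(s) with no neighbors: %s",
              paste(ws$adjacency$area_ids[islands], collapse = ", "))
  aw <- aligned_weights(ws)
  lapply(seq_along(aw), function(i) aw[[i]] / ws$w_plus[i])
}

#' Export pair weights as a CSV edge list
#'
#' @param ws a [weight_spec()].
#' @param path output CSV with columns `i`, `j`, `w` (1-based indices, one
#'   row per unordered pair).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(ws, path) {
  df <- data.frame(i = ws$pairs[, 1], j = ws$pairs[, 2], w = ws$w)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Import pair weights from a CSV edge list
#'
#' @param path CSV with columns `i`, `j`, `w`.
#' @param n number of areas.
#' @param scheme_label label for the resulting [weight_spec()].
#' @return a [weight_spec()] (the adjacency is implied by the edges).
#' @export
read_edge_list <- function(path, n, scheme_label = "custom") {
  df <- read.csv(path)
  if (!all(c("i", "j", "w") %in% names(df)))
    stop_data("edge list must have columns i, j, w")
  pr <- cbind(pmin(df$i, df$j), pmax(df$i, df$j))
  ord <- order(pr[, 1], pr[, 2])
  adj <- adjacency_from_pairs(n, pr[ord, , drop = FALSE])
  weight_spec(adj, df$w[ord], scheme_label = scheme_label)
}
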