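#' Construct a stratified population/case table
#'
#' Long-format table of person counts `N` and case counts `Y` per area and
#' age-sex stratum (the default study design: 2 sexes times 5 senior age
#' groups = 10 strata). Counts are events over the study period and are not
#' capped by `N`: a person can fall more than once, so `Y_ik > N_ik` is
#' admissible.
#'
#' @param df data.frame with columns `area_id`, `sex`, `age_group`, `N`, `Y`.
#' @param area_order optional character vector fixing the area ordering
#'   (default: order of first appearance).
#' @return object of class `stratum_table`: the validated data.frame with
#'   attributes `area_ids` and `strata`.
#' @export
stratum_table <- function(df, area_order = NULL) {
  need <- c("area_id", "sex", "age_group", "N", "Y")
  if (!all(need %in% names(df)))
    stop_data("stratum table needs columns: %s", paste(need, collapse = ", "))
  df$area_id <- as.character(df$area_id)
  if (any(df$N < 0) || any(df$Y < 0)) stop_data("counts must be nonnegative")
  if (any(df$N != round(df$N)) || any(df$Y != round(df$Y)))
    stop_data("counts must be integers")
  area_ids <- if (is.null(area_order)) unique(df$area_id) else as.character(area_order)
  if (!all(df$area_id %in% area_ids)) stop_data("area_order does not cover all areas")
  strata <- unique(paste(df$sex, df$age_group, sep = ":"))
  structure(df, class = c("stratum_table", "data.frame"),
            area_ids = area_ids, strata = strata)
}

# area x stratum matrix of one count column
stratum_matrix <- function(table, col) {
  area_ids <- attr(table, "area_ids")
  strata <- attr(table, "strata")
  m <- matrix(0, length(area_ids), length(strata),
              dimnames = list(area_ids, strata))
  key <- paste(table$sex, table$age_group, sep = ":")
  m[cbind(match(table$area_id, area_ids), match(key, strata))] <- table[[col]]
  m
}

#' Per-area totals of a stratum table
#'
#' @param table a [stratum_table()].
#' @return data.frame with `area_id`, total population `N`, total cases `Y`,
#'   in the table's area order.
#' @export
area_totals <- function(table) {
  N <- rowSums(stratum_matrix(table, "N"))
  Y <- rowSums(stratum_matrix(table, "Y"))
  data.frame(area_id = attr(table, "area_ids"), N = unname(N), Y = unname(Y))
}

#' Reference rates by internal indirect standardization
#'
#' Study-region stratum rates `z_k = sum_i Y_ik / sum_i N_ik`, the rates
#' against which area-level expected counts are computed.
#'
#' @param table a [stratum_table()].
#' @return named numeric vector of rates, one per stratum.
#' @export
reference_rates <- function(table) {
  Nk <- colSums(stratum_matrix(table, "N"))
  Yk <- colSums(stratum_matrix(table, "Y"))
  if (any(Nk == 0))
    stop_data("empty population in stratum(s): %s",
              paste(names(Nk)[Nk == 0], collapse = ", "))
  Yk / Nk
}

#' Expected counts under indirect standardization
#'
#' `E_i = sum_k N_ik z_k`. With internally standardized rates the identity
#' `sum(E) = sum(Y)` holds up to floating point.
#'
#' @param table a [stratum_table()].
#' @param z reference rates per stratum (default: [reference_rates()] of the
#'   table itself, i.e. internal standardization); an external rate table
#'   may be supplied as a named vector matching the table's strata.
#' @return named numeric vector `E` in the table's area order.
#' @export
expected_counts <- function(table, z = reference_rates(table)) {
  N <- stratum_matrix(table, "N")
  if (!is.null(names(z)) && all(colnames(N) %in% names(z))) z <- z[colnames(N)]
  if (length(z) != ncol(N))
    stop_data("need one rate per stratum (%d), got %d", ncol(N), length(z))
  drop(N %*% as.numeric(z))
}

#' Standardized incidence ratios
#'
#' `SIR_i = Y_i / E_i`. Division contract for zero expected counts: when
#' `E_i = 0` and `Y_i = 0` the ratio is reported as 0 and flagged
#' `"zero_expected"`; when `E_i = 0` with `Y_i > 0` it is undefined (`NA`)
#' and flagged `"undefined"`. No exceptions are raised.
#'
#' @param Y per-area observed totals.
#' @param E per-area expected counts.
#' @return data.frame with columns `sir` and `flag` (`"ok"`,
#'   `"zero_expected"`, `"undefined"`).
#' @export
sir <- function(Y, E) {
  if (length(Y) != length(E)) stop_data("Y and E lengths differ")
  s <- ifelse(E > 0, Y / E, ifelse(Y == 0, 0, NA_real_))
  flag <- ifelse(E > 0, "ok", ifelse(Y == 0, "zero_expected", "undefined"))
  data.frame(sir = s, flag = flag)
}

#' Read a stratum table from CSV
#'
#' @param path CSV with columns `area_id`, `sex`, `age_group`, `N`, `Y`.
#' @param area_order optional area ordering.
#' @return a [stratum_table()].
#' @export
read_stratum_table <- function(path, area_order = NULL) {
  stratum_table(read.csv(path, colClasses = c(area_id = "character")),
                area_order = area_order)
}

#' Write per-area expected counts and SIRs to CSV
#'
#' @param table a [stratum_table()].
#' @param path output CSV (`area_id`, `Y`, `E`, `sir`, `flag`).
#' @return the data.frame written, invisibly.
#' @export
write_standardization <- function(table, path) {
  tot <- area_totals(table)
  E <- expected_counts(table)
  s <- sir(tot$Y, E)
  out <- data.frame(area_id = tot$area_id, Y = tot$Y, E = unname(E),
                    sir = s$sir, flag = s$flag)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
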