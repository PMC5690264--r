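#' Construct an adjacency list
#'
#' Stores queen-contiguity (or any symmetric, self-loop-free) neighbourhood
#' structure in both graph form (`neighbors`, a list of 1-based index
#' vectors) and the flattened WinBUGS form (`num`, per-area neighbour counts,
#' and `adj`, the 1-based concatenation of the neighbour lists). Neighbour
#' entries are counted directed: the pair (i, j) contributes one entry to
#' area i's list and one to area j's, so `sum(num)` matches the convention
#' used when auditing adjacency totals.
#'
#' @param neighbors list of integer vectors, `neighbors[[i]]` the 1-based
#'   indices of the areas adjacent to area `i`.
#' @param area_ids optional identifiers carried along for reporting.
#' @return object of class `adjacency_list` with fields `n`, `neighbors`,
#'   `num`, `adj`, `area_ids`.
#' @export
adjacency_list <- function(neighbors, area_ids = NULL) {
  n <- length(neighbors)
  neighbors <- lapply(neighbors, function(v) sort(unique(as.integer(v))))
  for (i in seq_len(n)) {
    v <- neighbors[[i]]
    if (any(v < 1L | v > n)) stop_data("neighbor index out of range for area %d", i)
    if (i %in% v) stop_data("self-adjacency at area %d", i)
    for (j in v)
      if (!(i %in% neighbors[[j]]))
        stop_data("asymmetric adjacency: %d -> %d but not %d -> %d", i, j, j, i)
  }
  if (is.null(area_ids)) area_ids <- as.character(seq_len(n))
  structure(list(n = n,
                 neighbors = neighbors,
                 num = vapply(neighbors, length, integer(1)),
                 adj = as.integer(unlist(neighbors)),
                 area_ids = as.character(area_ids)),
            class = "adjacency_list")
}

#' @export
print.adjacency_list <- function(x, ...) {
  cat("adjacency_list:", x$n, "areas,", sum(x$num),
      "neighbor entries (", sum(x$num) / 2, "pairs )\n")
  invisible(x)
}

# unique unordered pairs (i < j) as a 2-column matrix
adjacency_pairs <- function(adj) {
  if (sum(adj$num) == 0L) return(matrix(integer(0), ncol = 2))
  i <- rep.int(seq_len(adj$n), adj$num)
  j <- adj$adj
  keep <- i < j
  cbind(i = i[keep], j = j[keep])
}

#' Build an adjacency list from unordered index pairs
#'
#' @param n number of areas.
#' @param pairs two-column matrix of 1-based area index pairs, one row per
#'   adjacent pair (order within a pair irrelevant).
#' @param area_ids optional identifiers.
#' @return an [adjacency_list()].
#' @export
adjacency_from_pairs <- function(n, pairs, area_ids = NULL) {
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  if (length(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
  }
  adjacency_list(nb, area_ids)
}

# is the adjacency graph connected? (BFS)
adjacency_connected <- function(adj) {
  if (adj$n == 0L) return(TRUE)
  seen <- logical(adj$n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj$neighbors[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

#' Extract queen-contiguity adjacency from a polygon map
#'
#' Two areas are treated as queen-contiguous when some vertex of one lies
#' within Euclidean distance `tolerance` of some vertex of the other. With
#' `tolerance = 0` vertices must match exactly after canonical rounding to
#' 1e-9 coordinate units, which is the strict behaviour that makes the
#' extraction sensitive to digitisation discrepancies: a shared boundary
#' vertex recorded with slightly different coordinates in the two polygons
#' is missed, and the affected pair is dropped from the neighbourhood
#' structure. A positive tolerance recovers such pairs.
#'
#' Candidate pairs are pruned by bounding-box overlap (boxes expanded by
#' `tolerance`); pruning cannot change the result because two vertices
#' within `tolerance` force the expanded boxes to overlap.
#'
#' @param map an [area_map()].
#' @param tolerance nonnegative matching distance in map units.
#' @return an [adjacency_list()].
#' @export
extract_queen_adjacency <- function(map, tolerance = 0) {
  if (!inherits(map, "area_map")) stop_data("map must be an area_map")
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance < 0)
    stop_config("tolerance must be a single nonnegative number")
  n <- length(map$area_ids)
  verts <- lapply(seq_len(n), function(i) map_vertices(map, i))
  if (tolerance == 0) verts <- lapply(verts, function(v) round(v, 9))

  bb <- t(vapply(verts, function(v)
    c(min(v[, 1]), max(v[, 1]), min(v[, 2]), max(v[, 2])), numeric(4)))
  tol <- tolerance
  pairs <- NULL
  for (i in seq_len(max(n - 1L, 0L))) {
    js <- which(bb[, 1] <= bb[i, 2] + tol & bb[, 2] >= bb[i, 1] - tol &
                bb[, 3] <= bb[i, 4] + tol & bb[, 4] >= bb[i, 3] - tol)
    js <- js[js > i]
    for (j in js) {
      dx <- outer(verts[[i]][, 1], verts[[j]][, 1], "-")
      dy <- outer(verts[[i]][, 2], verts[[j]][, 2], "-")
      d2 <- dx * dx + dy * dy
      hit <- if (tolerance == 0) any(d2 == 0) else any(d2 <= tol * tol)
      if (hit) pairs <- rbind(pairs, c(i, j))
    }
  }
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
  adjacency_from_pairs(n, pairs, map$area_ids)
}

#' Audit a generated adjacency list against a reference
#'
#' Compares a generated neighbourhood structure with the true one for the
#' same map and reports totals (directed neighbour entries), the pair sets
#' missed and invented, and the undercount error
#' `(total_true - total_generated) / total_true`.
#'
#' @param true_list,generated_list [adjacency_list()] objects over the same
#'   areas in the same order.
#' @return object of class `discrepancy_report` with fields `total_true`,
#'   `total_generated`, `missing_pairs`, `extra_pairs`, `undercount_error`.
#' @export
compare_adjacency <- function(true_list, generated_list) {
  if (true_list$n != generated_list$n)
    stop_data("adjacency lists cover different numbers of areas (%d vs %d)",
              true_list$n, generated_list$n)
  key <- function(p) if (nrow(p)) paste(p[, 1], p[, 2]) else character(0)
  pt <- adjacency_pairs(true_list); pg <- adjacency_pairs(generated_list)
  kt <- key(pt); kg <- key(pg)
  missing <- pt[!(kt %in% kg), , drop = FALSE]
  extra <- pg[!(kg %in% kt), , drop = FALSE]
  total_true <- sum(true_list$num)
  total_generated <- sum(generated_list$num)
  structure(list(total_true = total_true,
                 total_generated = total_generated,
                 missing_pairs = missing,
                 extra_pairs = extra,
                 undercount_error = (total_true - total_generated) / total_true),
            class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat(sprintf("adjacency audit: %d true vs %d generated neighbor entries\n",
              x$total_true, x$total_generated))
  cat(sprintf("  undercount error: %.4f (%.1f%%)\n",
              x$undercount_error, 100 * x$undercount_error))
  cat(sprintf("  pairs missed: %d, pairs invented: %d\n",
              nrow(x$missing_pairs), nrow(x$extra_pairs)))
  invisible(x)
}

#' Write adjacency (and optional weights) in WinBUGS format
#'
#' Emits the flattened `num`/`adj`(/`weights`) vectors as the S-PLUS style
#' list consumed by WinBUGS's `car.normal` distribution; `adj` is 1-based
#' and `weights` is aligned element-for-element with `adj`.
#'
#' @param adj an [adjacency_list()].
#' @param weights optional [weight_spec()] over the same adjacency.
#' @param path optional output file; when `NULL` the text is returned.
#' @return the file text, invisibly when written to `path`.
#' @export
write_winbugs_adjacency <- function(adj, weights = NULL, path = NULL) {
  fmt_num <- function(v) paste0("c(", paste(format(v, scientific = FALSE, trim = TRUE),
                                            collapse = ", "), ")")
  parts <- c(sprintf("num = %s", fmt_num(adj$num)),
             sprintf("adj = %s", fmt_num(adj$adj)))
  if (!is.null(weights)) {
    w <- aligned_weights_flat(weights)
    if (length(w) != length(adj$adj))
      stop_data("weight count (%d) does not match adjacency entries (%d)",
                length(w), length(adj$adj))
    parts <- c(parts, sprintf("weights = %s", fmt_num(w)))
  }
  parts <- c(parts, sprintf("sumNumNeigh = %d", sum(adj$num)))
  text <- paste0("list(", paste(parts, collapse = ",\n     "), ")\n")
  if (is.null(path)) return(text)
  writeLines(text, path)
  invisible(text)
}

#' Read a WinBUGS adjacency file
#'
#' Parses the `list(num = ..., adj = ..., weights = ..., sumNumNeigh = ...)`
#' text emitted by [write_winbugs_adjacency()] (and by common GIS adjacency
#' exporters). Round-trips with the writer.
#'
#' @param path file path, or a character string containing the list text.
#' @return list with components `adjacency` (an [adjacency_list()]) and
#'   `weights` (a [weight_spec()], or `NULL` when the file has none).
#' @export
read_winbugs_adjacency <- function(path) {
  text <- if (length(path) == 1 && file.exists(path))
    paste(readLines(path), collapse = "\n") else paste(path, collapse = "\n")
  expr <- tryCatch(str2lang(text), error = function(e)
    stop_data("cannot parse WinBUGS adjacency text: %s", conditionMessage(e)))
  vals <- eval(expr, envir = baseenv())
  num <- as.integer(vals$num)
  adjv <- as.integer(vals$adj)
  if (length(adjv) != sum(num))
    stop_data("length(adj) = %d but sum(num) = %d", length(adjv), sum(num))
  nb <- split(adjv, rep.int(seq_along(num), num))
  neighbors <- vector("list", length(num))
  for (i in seq_along(num)) neighbors[[i]] <- integer(0)
  neighbors[as.integer(names(nb))] <- nb
  al <- adjacency_list(neighbors)
  ws <- NULL
  if (!is.null(vals$weights)) {
    w <- as.numeric(vals$weights)
    if (length(w) != length(adjv))
      stop_data("weight count (%d) does not match adjacency entries (%d)",
                length(w), length(adjv))
    pr <- adjacency_pairs(al)
    # take each pair's weight from the first directed occurrence
    i <- rep.int(seq_along(num), num)
    keymap <- setNames(w, paste(pmin(i, adjv), pmax(i, adjv)))
    ws <- weight_spec(al, keymap[paste(pr[, 1], pr[, 2])], scheme_label = "custom")
  }
  list(adjacency = al, weights = ws)
}
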