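#' Construct an area map
#'
#' An `area_map` is an ordered collection of areas, each a polygon made of one
#' or more closed coordinate rings in planar units. It is the input to
#' [extract_queen_adjacency()] and the output of [generate_lattice_map()].
#'
#' @param area_ids character or integer vector of unique area identifiers.
#' @param polygons list (one element per area) of lists of rings; each ring a
#'   numeric matrix with two columns (x, y) whose first and last vertices
#'   coincide and which has at least 3 distinct vertices.
#' @return an object of class `area_map`.
#' @export
area_map <- function(area_ids, polygons) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) stop_data("area_ids must be unique")
  if (length(area_ids) != length(polygons))
    stop_data("one polygon per area_id required")
  polygons <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(p)
    lapply(p, function(ring) {
      ring <- as.matrix(ring)
      if (ncol(ring) != 2) stop_data("rings must have two coordinate columns")
      if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ], check.attributes = FALSE)))
        stop_data("rings must be closed (first vertex = last vertex)")
      if (nrow(unique(ring)) < 3) stop_data("rings need >= 3 distinct vertices")
      storage.mode(ring) <- "double"
      dimnames(ring) <- NULL
      ring
    })
  })
  structure(list(area_ids = area_ids, polygons = polygons), class = "area_map")
}

#' @export
print.area_map <- function(x, ...) {
  cat("area_map:", length(x$area_ids), "areas\n")
  invisible(x)
}

#' @export
length.area_map <- function(x) length(x$area_ids)

# unique vertices of an area (closing vertex dropped, all rings pooled)
map_vertices <- function(map, i) {
  v <- do.call(rbind, lapply(map$polygons[[i]], function(r) r[-nrow(r), , drop = FALSE]))
  unique(v)
}

# signed shoelace area of the outer ring, absolute value
polygon_area <- function(map, i = NULL) {
  one <- function(rings) {
    r <- rings[[1]]
    x <- r[-nrow(r), 1]; y <- r[-nrow(r), 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
  if (is.null(i)) vapply(map$polygons, one, numeric(1)) else one(map$polygons[[i]])
}

#' Write an area map as GeoJSON
#'
#' @param map an [area_map()].
#' @param path output file; contents are a GeoJSON `FeatureCollection` of
#'   `Polygon` features with an `area_id` property.
#' @param metadata optional named list stored under the collection's
#'   `properties` (e.g. scenario and seed of a synthetic map).
#' @return `path`, invisibly.
#' @export
write_area_map_geojson <- function(map, path, metadata = NULL) {
  features <- lapply(seq_along(map$area_ids), function(i) {
    rings <- lapply(map$polygons[[i]], function(r) {
      lapply(seq_len(nrow(r)), function(k) c(r[k, 1], r[k, 2]))
    })
    list(type = "Feature",
         properties = list(area_id = map$area_ids[i]),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  fc <- list(type = "FeatureCollection", features = features)
  if (!is.null(metadata)) fc$properties <- metadata
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an area map from GeoJSON
#'
#' Accepts `Polygon` and `MultiPolygon` features; the `area_id` property (or,
#' failing that, the feature index) names each area.
#'
#' @param path GeoJSON file.
#' @return an [area_map()].
#' @export
read_area_map_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$features)) stop_data("not a GeoJSON FeatureCollection: %s", path)
  ids <- character(0)
  polys <- list()
  ring_to_matrix <- function(ring)
    do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
  for (k in seq_along(fc$features)) {
    ft <- fc$features[[k]]
    id <- ft$properties$area_id
    if (is.null(id)) id <- as.character(k)
    geom <- ft$geometry
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ring_to_matrix),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(p) lapply(p, ring_to_matrix)),
                            recursive = FALSE),
      stop_data("unsupported geometry type '%s'", geom$type))
    ids <- c(ids, id)
    polys <- c(polys, list(rings))
  }
  area_map(ids, polys)
}
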