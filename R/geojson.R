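# GeoJSON FeatureCollection I/O (planar coordinates; Point, LineString and
# Polygon outer rings only — the subset the pipeline produces and consumes).

geom_to_geojson <- function(g) {
  coords <- unname(g$coords)
  switch(g$type,
    point = list(type = "Point", coordinates = coords[1, ]),
    line  = list(type = "LineString", coordinates = coords),
    polygon = {
      ring <- rbind(coords, coords[1, , drop = FALSE])   # close the ring
      list(type = "Polygon", coordinates = list(ring))
    })
}

geojson_to_geom <- function(gj) {
  type <- gj$type
  if (type == "Point") {
    geom("point", matrix(unlist(gj$coordinates), ncol = 2))
  } else if (type == "LineString") {
    geom("line", coord_matrix(gj$coordinates))
  } else if (type == "Polygon") {
    geom("polygon", coord_matrix(gj$coordinates[[1]]))
  } else {
    stop("unsupported GeoJSON geometry type: ", type, call. = FALSE)
  }
}

coord_matrix <- function(coords) {
  if (is.matrix(coords)) return(coords)                 # jsonlite simplification
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

#' Write / read threat features as GeoJSON
#'
#' Each feature carries `threat`, `category` and (when present) `attribute`
#' properties. Coordinates are planar meters in the run's projected CRS; no
#' reprojection is performed.
#'
#' @param features A `threat_features` collection.
#' @param path File path (`.geojson`).
#' @return `write_features_geojson` returns `path` invisibly;
#'   `read_features_geojson` returns a `threat_features` collection.
#' @export
write_features_geojson <- function(features, path) {
  stopifnot(inherits(features, "threat_features"))
  feats <- lapply(seq_len(nrow(features)), function(i) {
    props <- list(threat = features$threat[i], category = features$category[i])
    if (!is.na(features$attribute[i])) props$attribute <- features$attribute[i]
    list(type = "Feature", properties = props,
         geometry = geom_to_geojson(features$geometry[[i]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_features_geojson
#' @param registry Registry for key validation on read (`NULL` to skip).
#' @export
read_features_geojson <- function(path, registry = default_threat_registry()) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  n <- length(fc$features)
  if (n == 0L)
    return(threat_features(character(), character(), list(),
                           registry = registry))
  threat <- character(n); category <- character(n)
  attribute <- rep(NA_real_, n); geometry <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fc$features[[i]]
    threat[i] <- f$properties$threat
    category[i] <- f$properties$category
    if (!is.null(f$properties$attribute))
      attribute[i] <- as.numeric(f$properties$attribute)
    geometry[[i]] <- geojson_to_geom(f$geometry)
  }
  threat_features(threat, category, geometry, attribute, registry = registry)
}

#' Write / read microbasin polygons as GeoJSON
#'
#' @param basins A `microbasins` object (see [tile_microbasins()]): a list
#'   with `id` (character vector) and `polygon` (list of polygon [geom()]s),
#'   plus optional per-basin attribute columns in `attributes` (data frame).
#' @param path File path.
#' @return `write_microbasins_geojson` returns `path` invisibly;
#'   `read_microbasins_geojson` returns a `microbasins` object.
#' @export
write_microbasins_geojson <- function(basins, path) {
  stopifnot(inherits(basins, "microbasins"))
  attrs <- basins$attributes
  feats <- lapply(seq_along(basins$id), function(i) {
    props <- list(id = basins$id[i])
    if (!is.null(attrs) && nrow(attrs))
      props <- c(props, as.list(attrs[i, , drop = FALSE]))
    list(type = "Feature", properties = props,
         geometry = geom_to_geojson(basins$polygon[[i]]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_microbasins_geojson
#' @export
read_microbasins_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- length(fc$features)
  id <- character(n); polygon <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fc$features[[i]]
    id[i] <- as.character(f$properties$id)
    polygon[[i]] <- geojson_to_geom(f$geometry)
  }
  microbasins(id, polygon)
}

#' Construct a microbasin set
#'
#' @param id Character vector of basin ids.
#' @param polygon List of polygon [geom()]s, same length.
#' @param attributes Optional data frame of per-basin attributes.
#' @return An object of class `microbasins`.
#' @export
microbasins <- function(id, polygon, attributes = NULL) {
  stopifnot(length(id) == length(polygon),
            all(vapply(polygon, function(g)
      inherits(g, "geom") && g$type == "polygon", TRUE)))
  structure(list(id = as.character(id), polygon = polygon,
                 attributes = attributes),
            class = "microbasins")
}

#' @export
print.microbasins <- function(x, ...) {
  cat(sprintf("microbasins: %d polygons\n", length(x$id)))
  invisible(x)
}
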