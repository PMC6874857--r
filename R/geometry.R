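# Minimal planar geometry on projected coordinates (meters).
# Geometries are lists: list(type = "point"|"line"|"polygon", coords = matrix)
# with coords a two-column (x, y) matrix; polygon rings need not repeat the
# first vertex. No holes, no multipart geometries.

#' Construct a planar geometry
#'
#' @param type One of `"point"`, `"line"`, `"polygon"`.
#' @param coords Two-column numeric matrix of (x, y) vertices in meters.
#'   A point has one row; a line at least two; a polygon at least three
#'   (outer ring, closed implicitly).
#' @return An object of class `geom`.
#' @export
geom <- function(type = c("point", "line", "polygon"), coords) {
  type <- match.arg(type)
  coords <- matrix(as.numeric(coords), ncol = 2)
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  min_rows <- c(point = 1L, line = 2L, polygon = 3L)[[type]]
  if (nrow(coords) < min_rows)
    stop(sprintf("a %s needs at least %d vertices", type, min_rows),
         call. = FALSE)
  # drop an explicitly closed polygon's repeated last vertex
  if (type == "polygon" && nrow(coords) > 3L &&
      all(coords[1L, ] == coords[nrow(coords), ]))
    coords <- coords[-nrow(coords), , drop = FALSE]
  structure(list(type = type, coords = coords), class = "geom")
}

# squared distance from points (px, py) to segment (ax,ay)-(bx,by)
dist2_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

# distance from each point to the nearest vertex/edge of a vertex chain
dist_to_chain <- function(px, py, coords, closed = FALSE) {
  n <- nrow(coords)
  if (n == 1L) return(sqrt((px - coords[1, 1])^2 + (py - coords[1, 2])^2))
  i1 <- seq_len(n - 1L); i2 <- i1 + 1L
  if (closed) { i1 <- c(i1, n); i2 <- c(i2, 1L) }
  d2 <- Inf
  for (s in seq_along(i1)) {
    d2 <- pmin(d2, dist2_point_segment(px, py,
                                       coords[i1[s], 1], coords[i1[s], 2],
                                       coords[i2[s], 1], coords[i2[s], 2]))
  }
  sqrt(d2)
}

#' Point-in-polygon test (even-odd rule)
#'
#' Crossing-number test on the polygon's outer ring. Points exactly on an
#' edge count as inside (distance zero is what downstream decay needs).
#'
#' @param px,py Point coordinates (equal-length vectors).
#' @param polygon A `geom` of type `"polygon"`.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, polygon) {
  stopifnot(inherits(polygon, "geom"), polygon$type == "polygon")
  xs <- polygon$coords[, 1]; ys <- polygon$coords[, 2]
  n <- length(xs)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  on_edge <- dist_to_chain(px, py, polygon$coords, closed = TRUE) == 0
  inside | on_edge
}

#' Euclidean distance from points to a geometry
#'
#' Edge distance for lines and polygon boundaries; zero for points inside a
#' polygon. This is the distance fed to the linear impact decay.
#'
#' @param px,py Point coordinates (equal-length vectors).
#' @param geometry A `geom`.
#' @return Numeric vector of distances in the coordinate units (m).
#' @export
geom_distance <- function(px, py, geometry) {
  stopifnot(inherits(geometry, "geom"))
  d <- switch(geometry$type,
    point   = sqrt((px - geometry$coords[1, 1])^2 +
                   (py - geometry$coords[1, 2])^2),
    line    = dist_to_chain(px, py, geometry$coords, closed = FALSE),
    polygon = dist_to_chain(px, py, geometry$coords, closed = TRUE))
  if (geometry$type == "polygon")
    d[point_in_polygon(px, py, geometry)] <- 0
  d
}

# bounding box (xmin, ymin, xmax, ymax)
geom_bbox <- function(geometry) {
  c(min(geometry$coords[, 1]), min(geometry$coords[, 2]),
    max(geometry$coords[, 1]), max(geometry$coords[, 2]))
}
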