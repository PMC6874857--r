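# Spatial statistics: global Moran's I with analytic Z score, and the
# regional scale — site-to-microbasin assignment and zonal means.

#' Spatial weight matrices
#'
#' Builders for the weight schemes used by [morans_i()]: inverse Euclidean
#' distance (the common desktop-GIS default), rook contiguity on a regular
#' grid, and a fixed distance band. All have zero diagonal.
#'
#' @param coords Two-column (x, y) matrix of locations.
#' @param min_distance Distance floor (m) applied before inversion so
#'   coincident or near-coincident points get a finite weight.
#' @param row_standardize Scale each row to sum to 1.
#' @return An n x n numeric weight matrix.
#' @export
inverse_distance_weights <- function(coords, min_distance = 1,
                                     row_standardize = FALSE) {
  d <- as.matrix(stats::dist(coords))
  d <- pmax(d, min_distance)
  w <- 1 / d
  diag(w) <- 0
  finish_weights(w, row_standardize)
}

#' @rdname inverse_distance_weights
#' @param nrow,ncol Grid dimensions; cells are ordered row-major (row 1
#'   first).
#' @export
rook_weights <- function(nrow, ncol, row_standardize = FALSE) {
  n <- nrow * ncol
  w <- matrix(0, n, n)
  idx <- function(r, c) (r - 1L) * ncol + c
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    i <- idx(r, c)
    if (r > 1L) w[i, idx(r - 1L, c)] <- 1
    if (r < nrow) w[i, idx(r + 1L, c)] <- 1
    if (c > 1L) w[i, idx(r, c - 1L)] <- 1
    if (c < ncol) w[i, idx(r, c + 1L)] <- 1
  }
  finish_weights(w, row_standardize)
}

#' @rdname inverse_distance_weights
#' @param band Radius (m) within which pairs get weight 1.
#' @export
distance_band_weights <- function(coords, band, row_standardize = FALSE) {
  d <- as.matrix(stats::dist(coords))
  w <- (d <= band) * 1
  diag(w) <- 0
  finish_weights(w, row_standardize)
}

finish_weights <- function(w, row_standardize) {
  if (row_standardize) {
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    w <- w / rs
  }
  w
}

#' Global Moran's I with analytic Z score
#'
#' I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2
#' with S0 the sum of all weights. The expectation under no autocorrelation
#' is -1/(n-1); the variance is computed under the normality assumption by
#' default (randomization variant available), giving Z = (I - E\[I\]) / sd.
#'
#' @param x Numeric values at the locations (non-constant, n >= 4).
#' @param weights n x n spatial weight matrix (zero diagonal), e.g. from
#'   [inverse_distance_weights()].
#' @param assumption `"normality"` (default) or `"randomization"` variance.
#' @return A list with `I`, `expected`, `variance`, `z`, `p` (two-sided
#'   normal) and `n`.
#' @export
morans_i <- function(x, weights, assumption = c("normality", "randomization")) {
  assumption <- match.arg(assumption)
  n <- length(x)
  if (n < 4L) stop("Moran's I needs n >= 4", call. = FALSE)
  stopifnot(is.matrix(weights), nrow(weights) == n, ncol(weights) == n)
  if (any(diag(weights) != 0)) stop("weight matrix must have zero diagonal",
                                    call. = FALSE)
  z <- x - mean(x)
  if (all(z == 0)) stop("constant values: Moran's I undefined", call. = FALSE)
  s0 <- sum(weights)
  num <- as.numeric(t(z) %*% weights %*% z)
  I <- (n / s0) * num / sum(z^2)
  EI <- -1 / (n - 1)
  s1 <- sum((weights + t(weights))^2) / 2
  s2 <- sum((rowSums(weights) + colSums(weights))^2)
  if (assumption == "normality") {
    VI <- (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - EI^2
  } else {
    b2 <- n * sum(z^4) / sum(z^2)^2
    VI <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
             b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * s0^2) - EI^2
  }
  zscore <- (I - EI) / sqrt(VI)
  list(I = I, expected = EI, variance = VI, z = zscore,
       p = 2 * stats::pnorm(-abs(zscore)), n = n)
}

#' Assign sites to microbasins
#'
#' Maps each site to the polygon containing it (point-in-polygon, even-odd
#' rule; edge points count as inside). With overlapping polygons the first
#' containing polygon wins, with a warning. Sites in no polygon are reported
#' and excluded.
#'
#' @param sites Data frame with `site_id`, `x`, `y`.
#' @param basins A `microbasins` object.
#' @return A list with `membership` (data frame `site_id`, `basin_id`) and
#'   `unassigned` (character vector of site ids).
#' @export
assign_sites_to_microbasins <- function(sites, basins) {
  stopifnot(inherits(basins, "microbasins"))
  n <- nrow(sites)
  basin_id <- rep(NA_character_, n)
  multi <- FALSE
  for (b in seq_along(basins$id)) {
    inside <- point_in_polygon(sites$x, sites$y, basins$polygon[[b]])
    multi <- multi || any(inside & !is.na(basin_id))
    take <- inside & is.na(basin_id)
    basin_id[take] <- basins$id[b]
  }
  if (multi)
    warning("overlapping microbasin polygons: first containing polygon kept",
            call. = FALSE)
  unassigned <- as.character(sites$site_id[is.na(basin_id)])
  list(membership = data.frame(site_id = sites$site_id[!is.na(basin_id)],
                               basin_id = basin_id[!is.na(basin_id)],
                               stringsAsFactors = FALSE),
       unassigned = unassigned)
}

#' Aggregate sites and surfaces to the microbasin scale
#'
#' The regional analysis unit: per microbasin, the response is the mean EII
#' over member sites; predictors are zonal means over the pixels whose
#' centers fall inside the polygon. Microbasins with no member site carry
#' predictors but an NA response (usable for prediction, excluded from
#' model fitting).
#'
#' @param site_eii Data frame with `site_id` and `eii` (any extra columns
#'   ignored).
#' @param surfaces Named list of `impact_surface`s sharing one grid
#'   (threat and/or environmental layers).
#' @param basins A `microbasins` object.
#' @param membership Result of [assign_sites_to_microbasins()] on the same
#'   sites and basins.
#' @return Data frame, one row per microbasin: `basin_id`, `n_sites`,
#'   `eii` (NA when no sites), and one zonal-mean column per surface.
#' @export
aggregate_microbasins <- function(site_eii, surfaces, basins, membership) {
  stopifnot(inherits(basins, "microbasins"), length(surfaces) >= 1L)
  g <- surfaces[[1]]$grid
  for (s in surfaces)
    stopifnot(identical(s$grid[c("origin_x", "origin_y", "pixel_size",
                                 "ncol", "nrow")],
                        g[c("origin_x", "origin_y", "pixel_size",
                            "ncol", "nrow")]))
  ctr <- pixel_centers(g)
  nb <- length(basins$id)
  out <- data.frame(basin_id = basins$id, n_sites = 0L, eii = NA_real_,
                    stringsAsFactors = FALSE)
  for (nm in names(surfaces)) out[[nm]] <- NA_real_
  memb <- membership$membership
  for (b in seq_len(nb)) {
    inside <- point_in_polygon(ctr[, 1], ctr[, 2], basins$polygon[[b]])
    if (!any(inside))
      stop(sprintf("microbasin '%s' covers no pixel centers", basins$id[b]),
           call. = FALSE)
    for (nm in names(surfaces))
      out[[nm]][b] <- mean(surfaces[[nm]]$values[inside])
    ids <- memb$site_id[memb$basin_id == basins$id[b]]
    out$n_sites[b] <- length(ids)
    if (length(ids))
      out$eii[b] <- mean(site_eii$eii[match(ids, site_eii$site_id)])
  }
  out
}

#' Tile a grid into rectangular synthetic microbasins
#'
#' A stand-in for hydrologically delineated microbasin polygons: partitions
#' the grid extent into an `nx` x `ny` checkerboard of rectangles. Useful
#' for tests and synthetic regional-scale runs; real microbasin polygons are
#' supplied as GeoJSON.
#'
#' @param grid A `grid_spec`.
#' @param nx,ny Number of tiles along x and y.
#' @return A `microbasins` object with ids `"mb_001"`, ...
#' @export
tile_microbasins <- function(grid, nx = 5, ny = 5) {
  stopifnot(inherits(grid, "grid_spec"), nx >= 1, ny >= 1)
  w <- grid$ncol * grid$pixel_size / nx
  h <- grid$nrow * grid$pixel_size / ny
  polys <- list(); ids <- character(0)
  k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1L
    x0 <- grid$origin_x + (i - 1) * w
    y0 <- grid$origin_y + (j - 1) * h
    polys[[k]] <- geom("polygon",
                       rbind(c(x0, y0), c(x0 + w, y0),
                             c(x0 + w, y0 + h), c(x0, y0 + h)))
    ids[k] <- sprintf("mb_%03d", k)
  }
  microbasins(ids, polys)
}
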