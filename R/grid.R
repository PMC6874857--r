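#' Define a regular analysis grid
#'
#' A grid of square pixels on a projected planar coordinate system (meters).
#' The default pixel size of 500 m gives ~0.25 km2 pixels, the working
#' resolution for threat surfaces and local-scale modeling.
#'
#' @param origin_x,origin_y Coordinates (m) of the lower-left corner of the
#'   grid (the outer corner of pixel \[1,1\]).
#' @param pixel_size Side length of a pixel in meters. Must be > 0.
#' @param ncol,nrow Number of pixel columns / rows. Both must be >= 2.
#' @param crs_note Free-text note naming the projected CRS; never used for
#'   computation (one planar CRS per run).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(0, 0, 500, 40, 40)
#' dim(pixel_centers(g))
#' @export
grid_spec <- function(origin_x = 0, origin_y = 0, pixel_size = 500,
                      ncol = 50, nrow = 50, crs_note = "local planar (m)") {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  ncol <- as.integer(ncol); nrow <- as.integer(nrow)
  if (ncol < 2L || nrow < 2L)
    stop("degenerate grid: need at least 2 pixels per axis", call. = FALSE)
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         pixel_size = as.numeric(pixel_size), ncol = ncol, nrow = nrow,
         crs_note = crs_note),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d pixels of %g m (extent %g x %g km), origin (%g, %g)\n",
              x$ncol, x$nrow, x$pixel_size,
              x$ncol * x$pixel_size / 1000, x$nrow * x$pixel_size / 1000,
              x$origin_x, x$origin_y))
  invisible(x)
}

#' Coordinates of all pixel centers
#'
#' @param grid A `grid_spec`.
#' @return A two-column matrix (x, y) with `nrow * ncol` rows, ordered so that
#'   row k corresponds to element k of a surface's value matrix read in R's
#'   column-major order (grid row from the bottom varies fastest).
#' @export
pixel_centers <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  cx <- grid$origin_x + (seq_len(grid$ncol) - 0.5) * grid$pixel_size
  cy <- grid$origin_y + (seq_len(grid$nrow) - 0.5) * grid$pixel_size
  cbind(x = rep(cx, each = grid$nrow), y = rep(cy, times = grid$ncol))
}

#' Construct an impact surface (or any single-band grid of values)
#'
#' @param values Numeric matrix, `nrow(grid)` x `ncol(grid)`; element \[i, j\]
#'   belongs to the pixel in the i-th row from the bottom edge and j-th
#'   column from the left edge of the grid.
#' @param grid A `grid_spec`.
#' @param name Band name, e.g. the threat name ("roads") or "elevation".
#' @param provenance Optional list recording how the surface was built
#'   (registry version, overlap policy, ...).
#' @return An object of class `impact_surface`.
#' @export
impact_surface <- function(values, grid, name = "surface", provenance = list()) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$nrow || ncol(values) != grid$ncol)
    stop("values matrix does not match grid dimensions", call. = FALSE)
  if (any(is.nan(values) | is.infinite(values)))
    stop("surface values must be finite (NA allowed for nodata)", call. = FALSE)
  structure(list(values = values, grid = grid, name = name,
                 provenance = provenance),
            class = "impact_surface")
}

#' @export
print.impact_surface <- function(x, ...) {
  cat(sprintf("impact_surface '%s': %d x %d pixels, range [%.4g, %.4g]\n",
              x$name, x$grid$nrow, x$grid$ncol,
              min(x$values), max(x$values)))
  invisible(x)
}

# row/col indices (from bottom-left) of the pixel containing each point;
# points exactly on an interior boundary go to the higher index, points on
# the outer edge are pulled into the outermost pixel (nearest-pixel rule).
point_to_pixel <- function(grid, x, y) {
  fx <- (x - grid$origin_x) / grid$pixel_size
  fy <- (y - grid$origin_y) / grid$pixel_size
  out <- fx < 0 | fy < 0 | fx > grid$ncol | fy > grid$nrow
  if (any(out))
    stop(sprintf("%d site(s) fall outside the grid extent", sum(out)),
         call. = FALSE)
  col <- pmin(grid$ncol, floor(fx) + 1L)
  row <- pmin(grid$nrow, floor(fy) + 1L)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Look up surface values at point locations
#'
#' Returns the value of the pixel containing each site (nearest pixel for
#' sites exactly on the grid's outer boundary). Sites outside the grid
#' extent are an error.
#'
#' @param surface An `impact_surface`.
#' @param x,y Site coordinates (m), equal-length numeric vectors.
#' @return Numeric vector of per-site values.
#' @export
sample_surface <- function(surface, x, y) {
  stopifnot(inherits(surface, "impact_surface"), length(x) == length(y))
  idx <- point_to_pixel(surface$grid, x, y)
  surface$values[idx]
}

#' Fraction of the grid affected by a threat
#'
#' The share of pixels whose value exceeds `threshold` — the "extent" summary
#' used to compare threat footprints (e.g. agriculture covering half a basin).
#'
#' @param surface An `impact_surface`.
#' @param threshold Strict lower bound; default 0 counts every pixel any
#'   feature's buffer reaches.
#' @return A single number in \[0, 1\].
#' @export
surface_extent_fraction <- function(surface, threshold = 0) {
  stopifnot(inherits(surface, "impact_surface"), threshold >= 0)
  mean(surface$values > threshold)
}

#' Write / read a surface as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows of values, top row first. Round-trips an [impact_surface()]
#' losslessly at full double precision.
#'
#' @param surface An `impact_surface`.
#' @param path Output file path.
#' @param nodata Value written for NA pixels.
#' @return `write_asc` returns `path` invisibly; `read_asc` returns an
#'   `impact_surface`.
#' @export
write_asc <- function(surface, path, nodata = -9999) {
  stopifnot(inherits(surface, "impact_surface"))
  g <- surface$grid
  v <- surface$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$ncol),
    sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", g$origin_y),
    sprintf("cellsize %.10g", g$pixel_size),
    sprintf("NODATA_value %.10g", nodata)), con)
  # .asc stores the top row first; values[nrow, ] is the top row
  for (i in rev(seq_len(g$nrow)))
    writeLines(paste(format(v[i, ], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @param name Band name to give the surface read from `path`.
#' @export
read_asc <- function(path, name = sub("\\.asc$", "", basename(path))) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- tolower(vapply(hdr, `[`, "", 1L))
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- key
  g <- grid_spec(val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]],
                 ncol = val[["ncols"]], nrow = val[["nrows"]])
  rows <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rows)            # top row first
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m[m == val[["nodata_value"]]] <- NA_real_
  impact_surface(m, g, name = name)
}
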