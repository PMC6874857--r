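# Threat surfaces: per-pixel sums of linearly distance-decayed impact
# magnitudes, evaluated at pixel centers, on a 0-1 scale.

#' Linearly decayed impact of a feature at a distance
#'
#' A feature of magnitude `m` and maximum impact distance `D` contributes
#' `m * (1 - d / D)` at distance `d < D` and 0 at `d >= D`. Distance is
#' Euclidean to the nearest point of the geometry; inside a polygon `d = 0`
#' and the full magnitude applies.
#'
#' @param magnitude Impact magnitude in (0, 1] (vector ok).
#' @param distance Distance(s) to the feature, m, >= 0.
#' @param max_distance Maximum impact distance D, m, > 0.
#' @return Impact value(s) in `[0, magnitude]`.
#' @examples
#' decayed_impact(0.65, 5000, 10000)  # 0.325
#' @export
decayed_impact <- function(magnitude, distance, max_distance) {
  if (any(max_distance <= 0)) stop("max_distance must be > 0", call. = FALSE)
  if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
  pmax(0, magnitude * (1 - distance / max_distance))
}

#' Rasterize one threat's features into an impact surface
#'
#' Every pixel center within a feature's buffer receives that feature's
#' linearly decayed magnitude; overlapping buffers add. Under the default
#' `"cap"` policy sums are truncated at 1 so the surface keeps the absolute
#' 0-1 interpretation of the registry magnitudes; `"rescale"` divides by the
#' global maximum instead (only when that maximum exceeds 1). Pixels outside
#' every buffer are exactly 0.
#'
#' @param features A `threat_features` collection; all rows must share one
#'   threat.
#' @param registry A `threat_registry`.
#' @param grid A `grid_spec`.
#' @param policy Overlap policy, `"cap"` (default) or `"rescale"`.
#' @return An `impact_surface` named after the threat.
#' @export
rasterize_threat <- function(features, registry, grid,
                             policy = c("cap", "rescale")) {
  policy <- match.arg(policy)
  stopifnot(inherits(features, "threat_features"), inherits(grid, "grid_spec"))
  threat <- unique(features$threat)
  if (length(threat) > 1L)
    stop("features span multiple threats: ", paste(threat, collapse = ", "),
         call. = FALSE)
  if (length(threat) == 0L) threat <- "empty"
  vals <- matrix(0, grid$nrow, grid$ncol)
  if (nrow(features)) {
    mags <- resolve_magnitude(features, registry)
    dists <- resolve_distance(features, registry)
    ctr <- pixel_centers(grid)
    for (i in seq_len(nrow(features))) {
      g <- features$geometry[[i]]
      # only pixels whose center can be within D of the feature's bbox
      bb <- geom_bbox(g)
      near <- ctr[, 1] >= bb[1] - dists[i] & ctr[, 1] <= bb[3] + dists[i] &
              ctr[, 2] >= bb[2] - dists[i] & ctr[, 2] <= bb[4] + dists[i]
      if (!any(near)) next
      d <- geom_distance(ctr[near, 1], ctr[near, 2], g)
      vals[near] <- vals[near] + decayed_impact(mags[i], d, dists[i])
    }
  }
  if (policy == "cap") {
    vals <- pmin(vals, 1)
  } else if (max(vals) > 1) {
    vals <- vals / max(vals)
  }
  impact_surface(vals, grid, name = threat,
                 provenance = list(policy = policy,
                                   n_features = nrow(features)))
}

#' Build all nine threat surfaces
#'
#' Splits a mixed feature collection by threat and rasterizes each; threats
#' with no features yield all-zero surfaces, so the predictor set always has
#' one column per registry threat.
#'
#' @inheritParams rasterize_threat
#' @return A named list of `impact_surface`s, one per threat in the registry
#'   (registry order).
#' @export
build_threat_surfaces <- function(features, registry = default_threat_registry(),
                                  grid = grid_spec(),
                                  policy = c("cap", "rescale")) {
  policy <- match.arg(policy)
  threats <- unique(registry$threat)
  out <- vector("list", length(threats))
  names(out) <- threats
  for (t in threats) {
    sub <- features[features$threat == t, , drop = FALSE]
    class(sub) <- class(features)
    s <- rasterize_threat(sub, registry, grid, policy)
    s$name <- t
    out[[t]] <- s
  }
  out
}
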