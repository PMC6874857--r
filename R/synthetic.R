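# Seeded synthetic landscapes: environmental rasters, threat features,
# sites, and EII simulated from a known linear model, so the whole pipeline
# is testable (and its parameter recovery measurable) without external GIS
# or field data.

#' Configuration for a synthetic landscape
#'
#' Defaults mirror the study scale the pipeline targets: a 40 x 40 km grid
#' of 500 m pixels (large enough that individual threat buffers stay local
#' features rather than basin-wide gradients), 140 river sites, nine threat
#' layers, and Gaussian noise
#' calibrated so the analytic R2 of the generating model
#' (var(signal) / (var(signal) + sigma^2)) is 0.25 — the weak local-scale
#' signal regime. True coefficients take the signs of the fitted
#' local-scale model: settlements, roads and oil depress EII, elevation
#' depresses it, slope raises it.
#'
#' @param grid A `grid_spec` (default 80 x 80 pixels of 500 m).
#' @param n_sites Number of river sites (>= 2; default 140).
#' @param feature_counts Named integer vector: features to draw per threat
#'   (`"roads"`, category drawn uniformly from the registry) or per
#'   category (`"human_settlements/village"`). The default mix is
#'   calibrated so threat footprints match the relative extents reported
#'   for Andean-Amazon basins: agriculture the most widespread (~half the
#'   basin), settlements ~a fifth, mining ~15%, oil ~10%, power plants and
#'   water users spatially limited.
#' @param beta0 True intercept on the EII scale.
#' @param beta Named numeric vector of true coefficients over predictors
#'   (threat names and/or `"elevation"`, `"slope"`), response-scale units
#'   per unit of 0-1-scaled predictor.
#' @param sigma Noise SD in EII units, or `NULL` to calibrate from
#'   `target_r2` at generation time.
#' @param target_r2 Analytic R2 used to set `sigma` when `sigma` is `NULL`.
#' @param seed Integer random seed; fixed seed implies bitwise-identical
#'   output.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid = grid_spec(0, 0, 500, 80, 80),
                             n_sites = 140,
                             feature_counts = c(
                               "human_settlements/urban_area" = 1,
                               "human_settlements/village" = 10,
                               "mining" = 4,
                               "agriculture" = 12,
                               "hydroelectric/operating_small" = 1,
                               "hydroelectric/construction_medium" = 1,
                               "thermoelectric" = 2,
                               "oil/well_operating" = 4,
                               "oil/well_not_operating" = 3,
                               "oil/spill_recent_high" = 1,
                               "oil/pool_no_treatment" = 1,
                               "oil/pipeline_risky" = 1,
                               "oil/pipeline_out_of_risk" = 1,
                               "water_withdrawals" = 5,
                               "aquaculture" = 5,
                               "roads" = 10),
                             beta0 = 0.762,
                             beta = c(human_settlements = -0.165,
                                      roads = -0.121, oil = -0.136,
                                      elevation = -0.176, slope = 0.199),
                             sigma = NULL, target_r2 = 0.25, seed = 42) {
  stopifnot(inherits(grid, "grid_spec"), n_sites >= 2,
            is.null(sigma) || sigma >= 0,
            is.null(target_r2) || (target_r2 > 0 && target_r2 < 1))
  if (is.null(names(beta)) || any(!nzchar(names(beta))))
    stop("beta must be a named vector", call. = FALSE)
  structure(list(grid = grid, n_sites = as.integer(n_sites),
                 feature_counts = feature_counts, beta0 = beta0, beta = beta,
                 sigma = sigma, target_r2 = target_r2,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate synthetic elevation and slope rasters
#'
#' Elevation is a smooth monotone gradient across the grid (high in one
#' corner, low in the opposite), concave along the descent so the terrain
#' is steep in the highlands and flattens toward the lowlands — which gives
#' the moderate positive elevation-slope correlation (~0.5) typical of
#' mountain-to-floodplain basins — plus low-frequency sinusoidal relief and
#' seeded noise. Slope (degrees) is derived from elevation by central
#' finite differences on the pixel lattice, one-sided at the edges.
#'
#' @param grid A `grid_spec`.
#' @param seed Integer seed.
#' @param relief Elevation drop (m) across the grid diagonal (default 3000,
#'   an Andean-foothills gradient).
#' @param base Elevation (m) of the lowest corner (default 300).
#' @param noise_sd SD (m) of the per-pixel noise added to the smooth field.
#' @return Named list of two `impact_surface`s, `elevation` (m) and `slope`
#'   (degrees).
#' @export
generate_env_rasters <- function(grid, seed = 1, relief = 3000, base = 300,
                                 noise_sd = 15) {
  stopifnot(inherits(grid, "grid_spec"))
  set.seed(seed)
  nr <- grid$nrow; nc <- grid$ncol
  fx <- matrix(rep((seq_len(nc) - 1) / (nc - 1), each = nr), nr, nc)
  fy <- matrix(rep((seq_len(nr) - 1) / (nr - 1), times = nc), nr, nc)
  u <- (fx + fy) / 2
  elev <- base + relief * u^2 +
    0.04 * relief * sin(6 * pi * fx) * cos(5 * pi * fy) +
    matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
  slope <- slope_from_elevation(elev, grid$pixel_size)
  list(elevation = impact_surface(elev, grid, "elevation"),
       slope = impact_surface(slope, grid, "slope"))
}

#' Slope (degrees) from an elevation matrix by central differences
#'
#' @param elev Elevation matrix (m), rows = grid rows from the bottom.
#' @param pixel_size Pixel size (m).
#' @return Matrix of slope angles in degrees:
#'   `atan(sqrt(dz/dx^2 + dz/dy^2))`.
#' @export
slope_from_elevation <- function(elev, pixel_size) {
  nr <- nrow(elev); nc <- ncol(elev)
  if (nr < 2 || nc < 2) stop("need at least 2 pixels per axis", call. = FALSE)
  ddim <- function(m, along) {
    n <- dim(m)[along]
    hi <- pmin(seq_len(n) + 1L, n)
    lo <- pmax(seq_len(n) - 1L, 1L)
    span <- (hi - lo) * pixel_size
    if (along == 1L) (m[hi, , drop = FALSE] - m[lo, , drop = FALSE]) / span
    else t(t(m[, hi, drop = FALSE] - m[, lo, drop = FALSE]) / span)
  }
  dzdy <- ddim(elev, 1L)
  dzdx <- ddim(elev, 2L)
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}

#' Draw random threat features across the grid
#'
#' Settlements, mining, power plants, oil wells/pools, withdrawals and farms
#' are points; roads and pipelines are polylines; agriculture patches are
#' rectangular polygons. Categories are drawn uniformly from the registry's
#' categories for each threat; attribute-scaled categories get water-volume
#' attributes drawn uniformly on \[1e3, 1e5\] m3.
#'
#' @param config A `synthetic_config`.
#' @param registry A `threat_registry` (defaults to the shipped registry).
#' @return A `threat_features` collection (deterministic in `config$seed`).
#' @export
generate_threat_features <- function(config,
                                     registry = default_threat_registry()) {
  stopifnot(inherits(config, "synthetic_config"))
  counts <- config$feature_counts
  if (any(counts < 0)) stop("feature counts must be >= 0", call. = FALSE)
  key_threat <- sub("/.*$", "", names(counts))
  key_cat <- ifelse(grepl("/", names(counts)),
                    sub("^[^/]*/", "", names(counts)), NA_character_)
  bad <- setdiff(key_threat, unique(registry$threat))
  if (length(bad))
    stop("threats not in registry: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (i in which(!is.na(key_cat)))
    registry_lookup(registry, key_threat[i], key_cat[i])
  set.seed(config$seed)
  g <- config$grid
  xmax <- g$origin_x + g$ncol * g$pixel_size
  ymax <- g$origin_y + g$nrow * g$pixel_size
  rx <- function(n) stats::runif(n, g$origin_x, xmax)
  ry <- function(n) stats::runif(n, g$origin_y, ymax)
  threat <- character(0); category <- character(0)
  attribute <- numeric(0); geometry <- list()
  for (key in seq_along(counts)) {
    t <- key_threat[key]
    cats <- if (is.na(key_cat[key])) registry$category[registry$threat == t]
            else key_cat[key]
    for (i in seq_len(counts[[key]])) {
      cat_i <- cats[sample.int(length(cats), 1L)]
      spec <- registry_lookup(registry, t, cat_i)
      gm <- if (t == "roads" || grepl("^pipeline", cat_i)) {
        # polyline wandering across the extent
        nv <- 4L
        geom("line", cbind(sort(rx(nv)), ry(nv)))
      } else if (t == "agriculture") {
        x0 <- stats::runif(1, g$origin_x, xmax - 2 * g$pixel_size)
        y0 <- stats::runif(1, g$origin_y, ymax - 2 * g$pixel_size)
        w <- stats::runif(1, g$pixel_size, min(4 * g$pixel_size, xmax - x0))
        h <- stats::runif(1, g$pixel_size, min(4 * g$pixel_size, ymax - y0))
        geom("polygon", rbind(c(x0, y0), c(x0 + w, y0),
                              c(x0 + w, y0 + h), c(x0, y0 + h)))
      } else {
        geom("point", cbind(rx(1), ry(1)))
      }
      a <- if (spec$magnitude_rule == "attribute")
        stats::runif(1, 1e3, 1e5) else NA_real_
      threat <- c(threat, t); category <- c(category, cat_i)
      attribute <- c(attribute, a)
      geometry[[length(geometry) + 1L]] <- gm
    }
  }
  threat_features(threat, category, geometry, attribute, registry = registry)
}

#' Simulate EII from a linear generating model
#'
#' `EII_i = beta0 + sum_j beta_j x_ij + eps_i`, `eps_i ~ N(0, sigma^2)`,
#' clamped into \[0, 1\] afterwards (the index is bounded by construction);
#' the number of clamped sites is reported.
#'
#' @param predictors Data frame of predictor values in \[0, 1\], columns
#'   covering `names(beta)`.
#' @param beta0 Intercept.
#' @param beta Named coefficient vector.
#' @param sigma Noise SD (>= 0).
#' @param seed Integer seed.
#' @return A list: `eii` (numeric vector), `signal` (noise-free linear
#'   predictor, unclamped), `n_clamped`.
#' @export
simulate_eii <- function(predictors, beta0, beta, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  predictors <- as.data.frame(predictors)
  missing <- setdiff(names(beta), names(predictors))
  if (length(missing))
    stop("predictors missing for coefficients: ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- as.matrix(predictors[names(beta)])
  if (any(X < -1e-9 | X > 1 + 1e-9))
    stop("predictor values must be scaled to [0, 1]", call. = FALSE)
  signal <- beta0 + as.numeric(X %*% beta)
  set.seed(seed)
  eii <- signal + stats::rnorm(length(signal), sd = sigma)
  clamped <- sum(eii < 0 | eii > 1)
  list(eii = pmin(1, pmax(0, eii)), signal = signal, n_clamped = clamped)
}

#' Generate a full synthetic landscape
#'
#' The stated world for pipeline tests: threat features and surfaces,
#' elevation/slope rasters, uniformly placed sites, per-site predictor
#' values sampled exactly as the real pipeline samples them (surface value
#' of the containing pixel, environment min-max scaled to \[0, 1\]), and EII
#' simulated from the configured linear model. When `config$sigma` is
#' `NULL`, sigma is set from the realized signal variance so that
#' `var(signal) / (var(signal) + sigma^2) = config$target_r2`.
#'
#' @param config A `synthetic_config`.
#' @param registry A `threat_registry`.
#' @return A list of class `synthetic_landscape`: `config`, `features`,
#'   `surfaces` (nine threats), `env` (elevation, slope), `sites` (data
#'   frame `site_id`, `x`, `y`, `elevation`, `eii`, `signal`), `predictors`
#'   (per-site data frame used in the generating model, 0-1 scale),
#'   `scaling` (environment scaling record), `beta0`, `beta`, `sigma`,
#'   `n_clamped`.
#' @export
generate_landscape <- function(config = synthetic_config(),
                               registry = default_threat_registry()) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- config$grid
  features <- generate_threat_features(config, registry)
  surfaces <- build_threat_surfaces(features, registry, g)
  env <- generate_env_rasters(g, seed = config$seed + 1L)

  set.seed(config$seed + 2L)
  xmax <- g$origin_x + g$ncol * g$pixel_size
  ymax <- g$origin_y + g$nrow * g$pixel_size
  n <- config$n_sites
  # site placement mirrors a stratified field design: half the sites are
  # spread uniformly, half deliberately cover the anthropogenic pressure
  # gradient (placed within a random feature's impact buffer) — purely
  # uniform placement undersamples spatially rare threats
  sx <- stats::runif(n, g$origin_x, xmax)
  sy <- stats::runif(n, g$origin_y, ymax)
  if (nrow(features)) {
    dists <- resolve_distance(features, registry)
    near <- which(seq_len(n) %% 2L == 0L)
    fi <- sample.int(nrow(features), length(near), replace = TRUE)
    ang <- stats::runif(length(near), 0, 2 * pi)
    rad <- stats::runif(length(near), 0, dists[fi])
    anchor <- t(vapply(features$geometry[fi], function(gm)
      colMeans(gm$coords), c(0, 0)))
    sx[near] <- pmin(xmax, pmax(g$origin_x, anchor[, 1] + rad * cos(ang)))
    sy[near] <- pmin(ymax, pmax(g$origin_y, anchor[, 2] + rad * sin(ang)))
  }
  sites <- data.frame(
    site_id = sprintf("site_%03d", seq_len(n)),
    x = sx, y = sy, stringsAsFactors = FALSE)
  sites$elevation <- sample_surface(env$elevation, sites$x, sites$y)

  raw <- data.frame(row.names = seq_len(config$n_sites))
  for (nm in names(surfaces))
    raw[[nm]] <- sample_surface(surfaces[[nm]], sites$x, sites$y)
  raw$elevation <- sites$elevation
  raw$slope <- sample_surface(env$slope, sites$x, sites$y)
  # every predictor is min-max scaled over its basin-wide (grid) range —
  # the convention of the fitted models, where all predictors (threat and
  # environmental alike) enter on a common 0-1 scale. Scaling by the grid
  # rather than the site sample means sampled sites rarely sit at the exact
  # extremes, keeping simulated EII off the bounds.
  predictors <- raw
  rec <- data.frame(column = names(raw),
                    min = 0, max = 1, stringsAsFactors = FALSE)
  all_layers <- c(surfaces, env)
  for (nm in names(all_layers)) {
    rng <- range(all_layers[[nm]]$values)
    if (rng[2] > rng[1]) {
      predictors[[nm]] <- (raw[[nm]] - rng[1]) / (rng[2] - rng[1])
      rec[rec$column == nm, c("min", "max")] <- as.list(rng)
    }
  }
  sc <- list(scaled = predictors, record = rec)

  sigma <- config$sigma
  signal_var <- stats::var(
    as.numeric(as.matrix(predictors[names(config$beta)]) %*% config$beta))
  if (is.null(sigma))
    sigma <- sqrt(signal_var * (1 - config$target_r2) / config$target_r2)
  sim <- simulate_eii(predictors, config$beta0, config$beta, sigma,
                      seed = config$seed + 3L)
  sites$eii <- sim$eii
  sites$signal <- sim$signal
  structure(list(config = config, features = features, surfaces = surfaces,
                 env = env, sites = sites, predictors = predictors,
                 scaling = sc$record, beta0 = config$beta0,
                 beta = config$beta, sigma = sigma,
                 n_clamped = sim$n_clamped),
            class = "synthetic_landscape")
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf(
    "synthetic_landscape: %d sites on a %d x %d grid, %d features, sigma = %.4f (%d clamped)\n",
    nrow(x$sites), x$config$grid$nrow, x$config$grid$ncol,
    nrow(x$features), x$sigma, x$n_clamped))
  invisible(x)
}

#' Synthetic family tolerance table
#'
#' Ten invertebrate families at every integer tolerance score 1..10 (100
#' families), so any target mean score in \[1, 10\] is approachable with a
#' 10-family assemblage to within 0.05 score units. A stand-in for a
#' published regional tolerance list, which is not redistributed here.
#'
#' @return Data frame `family`, `score`.
#' @export
synthetic_tolerance_table <- function() {
  scores <- rep(1:10, each = 10)
  data.frame(family = sprintf("fam_s%02d_%02d", scores, rep(1:10, times = 10)),
             score = scores, stringsAsFactors = FALSE)
}

#' Simulate raw site measurements that reproduce target component scores
#'
#' Inverse of the scoring pipeline, for round-trip testing: given target
#' (biotic, habitat, physchem) scores per site it constructs taxa lists
#' (10-family assemblages whose mean tolerance matches the target ASPT),
#' raw habitat scores, and physical-chemical observations offset from the
#' reference values, together with the fixed normalization bounds under
#' which [score_sites()] reproduces the targets to within 0.02.
#'
#' @param targets Data frame with columns `biotic`, `habitat`, `physchem`,
#'   all in \[0, 1\]; one row per site.
#' @param tolerance_table Tolerance table (default
#'   [synthetic_tolerance_table()]); must offer >= 10 families at both its
#'   minimum and maximum score for the extreme targets to be feasible.
#' @param references Reference values/bounds (default
#'   [default_reference_values()]).
#' @param richness Families per site (default 10).
#' @param seed Integer seed (site placement and which parameters absorb the
#'   deviations).
#' @return A list: `sites` (site table for [score_sites()]), `taxa`
#'   (long format), `scoring_args` (list of arguments — `biotic_bounds`,
#'   `physchem_bounds`, `habitat_max`, `references`, `tolerance_table` —
#'   that make the round trip exact).
#' @export
simulate_site_parameters <- function(targets,
                                     tolerance_table = synthetic_tolerance_table(),
                                     references = default_reference_values(),
                                     richness = 10, seed = 1) {
  stopifnot(all(c("biotic", "habitat", "physchem") %in% names(targets)))
  tv <- sort(as_tolerance_vector(tolerance_table))
  if (any(targets$biotic < 0 | targets$biotic > 1 |
          targets$habitat < 0 | targets$habitat > 1 |
          targets$physchem < 0 | targets$physchem > 1))
    stop("target component scores must lie in [0, 1]", call. = FALSE)
  smin <- min(tv); smax <- max(tv)
  if (sum(tv == smin) < richness || sum(tv == smax) < richness)
    stop(sprintf(
      "infeasible: need >= %d families at both extreme tolerance scores",
      richness), call. = FALSE)
  set.seed(seed)
  n <- nrow(targets)
  sites <- data.frame(site_id = sprintf("site_%03d", seq_len(n)),
                      x = stats::runif(n, 0, 1000),
                      y = stats::runif(n, 0, 1000),
                      stringsAsFactors = FALSE)
  # habitat: raw = target * max reproduces the target exactly
  sites$qbr <- targets$habitat * 100
  sites$ihf <- targets$habitat * 100
  # physchem: every parameter deviates by the same scaled amount
  for (p in references$parameter) {
    ref <- references[references$parameter == p, ]
    dev <- (1 - targets$physchem) * ref$bound
    sign <- sample(c(-1, 1), n, replace = TRUE)
    sites[[p]] <- ref$reference + sign * dev
  }
  # biotic: pick `richness` distinct families with mean score at the target
  taxa_site <- character(0); taxa_fam <- character(0)
  for (i in seq_len(n)) {
    target_mean <- smin + targets$biotic[i] * (smax - smin)
    fams <- pick_families(tv, richness, target_mean)
    taxa_site <- c(taxa_site, rep(sites$site_id[i], length(fams)))
    taxa_fam <- c(taxa_fam, fams)
  }
  list(sites = sites,
       taxa = data.frame(site_id = taxa_site, family = taxa_fam,
                         stringsAsFactors = FALSE),
       scoring_args = list(
         tolerance_table = tolerance_table,
         references = references,
         habitat_max = c(100, 100),
         physchem_bounds = "fixed",
         biotic_bounds = list(ambi = richness * c(smin, smax),
                              aspt = c(smin, smax))))
}

# greedy selection of `k` distinct families whose mean score tracks `target`
pick_families <- function(sorted_scores, k, target) {
  avail <- sorted_scores
  chosen <- character(0)
  total <- 0
  for (j in seq_len(k)) {
    want <- (target * k - total) / (k - j + 1)   # mean still needed per pick
    i <- which.min(abs(avail - want))
    chosen <- c(chosen, names(avail)[i])
    total <- total + avail[i]
    avail <- avail[-i]
  }
  chosen
}
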