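# Threat registry: per-(threat, category) impact magnitude m in (0,1], maximum
# impact distance D in meters, and the scaling rules for categories whose
# magnitude or distance is derived from a feature attribute.

#' The shipped default threat registry
#'
#' The nine freshwater threats and their categories with the magnitude of
#' impact (0-1 severity weight) and maximum impact distance (m) used to build
#' threat surfaces. Aquaculture farms and water withdrawals carry an
#' attribute-scaled magnitude (linear in water volume, output 0.1-1);
#' hydroelectric plants carry a distance scaled to plant size, largest
#' operating class at 30 km and other classes proportional to their
#' magnitude.
#'
#' @return A data frame of class `threat_registry` with columns `threat`,
#'   `category`, `magnitude`, `distance_m`, `magnitude_rule`
#'   (`"fixed"`/`"attribute"`), `attribute` (attribute name or NA),
#'   `mag_min`, `mag_max` (declared output interval for attribute scaling),
#'   and `distance_rule` (`"fixed"`/`"plant_size"`).
#' @export
default_threat_registry <- function() {
  r <- function(threat, category, magnitude, distance_m,
                magnitude_rule = "fixed", attribute = NA_character_,
                mag_min = NA_real_, mag_max = NA_real_,
                distance_rule = "fixed") {
    data.frame(threat = threat, category = category, magnitude = magnitude,
               distance_m = distance_m, magnitude_rule = magnitude_rule,
               attribute = attribute, mag_min = mag_min, mag_max = mag_max,
               distance_rule = distance_rule, stringsAsFactors = FALSE)
  }
  reg <- rbind(
    r("human_settlements", "urban_area", 0.65, 10000),
    r("human_settlements", "village",    0.35,  3000),
    r("mining", "construction_material", 0.6,  5000),
    r("mining", "metal",                 0.4,  5000),
    r("mining", "non_metal",             0.1,  5000),
    r("agriculture", "crops",            0.6,  5000),
    r("agriculture", "mosaic_pasture",   0.4,  5000),
    r("hydroelectric", "operating_large",      0.375, 30000, distance_rule = "plant_size"),
    r("hydroelectric", "operating_medium",     0.225, 30000, distance_rule = "plant_size"),
    r("hydroelectric", "operating_small",      0.15,  30000, distance_rule = "plant_size"),
    r("hydroelectric", "construction_large",   0.125, 30000, distance_rule = "plant_size"),
    r("hydroelectric", "construction_medium",  0.075, 30000, distance_rule = "plant_size"),
    r("hydroelectric", "construction_small",   0.05,  30000, distance_rule = "plant_size"),
    r("thermoelectric", "plant", 1, 2000),
    r("oil", "well_operating",      0.28,   1500),
    r("oil", "well_not_operating",  0.07,   1500),
    r("oil", "spill_recent_high",   0.15,   5000),
    r("oil", "spill_recent_low",    0.09,   5000),
    r("oil", "spill_old_high",      0.075,  5000),
    r("oil", "spill_old_low",       0.015,  5000),
    r("oil", "pool_no_treatment",   0.2,    5000),
    r("oil", "pool_recent_treated", 0.0625, 5000),
    r("oil", "pool_old_no_treatment", 0.0125, 5000),
    r("oil", "pipeline_risky",      0.07,     30),
    r("oil", "pipeline_out_of_risk", 0.03,    30),
    r("aquaculture", "farm", 1, 1000, magnitude_rule = "attribute",
      attribute = "water_volume_m3", mag_min = 0.1, mag_max = 1),
    r("water_withdrawals", "withdrawal", 1, 1000, magnitude_rule = "attribute",
      attribute = "water_volume_m3", mag_min = 0.1, mag_max = 1),
    r("roads", "primary",   0.5, 1000),
    r("roads", "secondary", 0.3, 1000),
    r("roads", "local",     0.2, 1000))
  class(reg) <- c("threat_registry", "data.frame")
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg))
  need <- c("threat", "category", "magnitude", "distance_m",
            "magnitude_rule", "attribute", "mag_min", "mag_max",
            "distance_rule")
  missing <- setdiff(need, names(reg))
  if (length(missing))
    stop("registry missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  key <- paste(reg$threat, reg$category, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate registry keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  if (any(reg$magnitude <= 0 | reg$magnitude > 1))
    stop("magnitudes must lie in (0, 1]", call. = FALSE)
  if (any(reg$distance_m <= 0))
    stop("impact distances must be positive", call. = FALSE)
  bad <- reg$magnitude_rule == "attribute" &
    (is.na(reg$attribute) | is.na(reg$mag_min) | is.na(reg$mag_max))
  if (any(bad))
    stop("attribute-scaled rows must declare attribute, mag_min, mag_max",
         call. = FALSE)
  invisible(reg)
}

registry_lookup <- function(reg, threat, category) {
  i <- which(reg$threat == threat & reg$category == category)
  if (length(i) != 1L)
    stop(sprintf("threat/category '%s/%s' not in registry", threat, category),
         call. = FALSE)
  reg[i, , drop = FALSE]
}

#' Read / write a threat registry as CSV
#'
#' The on-disk form mirrors the registry columns one-to-one; the shipped
#' default (see `system.file("extdata", "threat_registry.csv",
#' package = "ecointegrity")`) round-trips losslessly.
#'
#' @param path File path.
#' @return `read_threat_registry` returns a `threat_registry`;
#'   `write_threat_registry` returns `path` invisibly.
#' @export
read_threat_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  reg$attribute <- as.character(reg$attribute)
  for (col in c("magnitude", "distance_m", "mag_min", "mag_max"))
    reg[[col]] <- as.numeric(reg[[col]])
  class(reg) <- c("threat_registry", "data.frame")
  validate_registry(reg)
  reg
}

#' @rdname read_threat_registry
#' @param registry A `threat_registry`.
#' @export
write_threat_registry <- function(registry, path) {
  validate_registry(registry)
  utils::write.csv(registry, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Resolve per-feature impact magnitudes
#'
#' Fixed-rule categories return the registry magnitude verbatim.
#' Attribute-scaled categories (aquaculture farms and water withdrawals,
#' scaled by water volume) map the attribute linearly from its observed
#' min/max across the supplied feature set onto the declared output interval
#' (all-equal attributes map to the interval's upper end).
#'
#' @param features A `threat_features` collection (see [threat_features()]).
#' @param registry A `threat_registry`.
#' @return Numeric vector of magnitudes, one per feature.
#' @export
resolve_magnitude <- function(features, registry) {
  stopifnot(inherits(features, "threat_features"))
  out <- numeric(nrow(features))
  for (i in seq_len(nrow(features))) {
    spec <- registry_lookup(registry, features$threat[i], features$category[i])
    if (spec$magnitude_rule == "fixed") {
      out[i] <- spec$magnitude
    } else {
      a <- features$attribute[i]
      if (is.na(a))
        stop(sprintf("feature %d (%s/%s) needs attribute '%s'",
                     i, spec$threat, spec$category, spec$attribute),
             call. = FALSE)
      same <- features$threat == spec$threat & features$category == spec$category
      av <- features$attribute[same]
      if (any(is.na(av)))
        stop("attribute-scaled category has features with missing attribute",
             call. = FALSE)
      rng <- range(av)
      frac <- if (rng[2] > rng[1]) (a - rng[1]) / (rng[2] - rng[1]) else 1
      out[i] <- spec$mag_min + frac * (spec$mag_max - spec$mag_min)
    }
  }
  out
}

#' Resolve per-feature maximum impact distances
#'
#' Fixed-rule categories return the registry distance verbatim. The
#' hydroelectric plant-size rule scales the registry cap (30 km) by the
#' category magnitude relative to the largest operating class (0.375), so the
#' largest operating plants reach 30 km and smaller classes proportionally
#' less.
#'
#' @inheritParams resolve_magnitude
#' @return Numeric vector of distances (m), one per feature.
#' @export
resolve_distance <- function(features, registry) {
  stopifnot(inherits(features, "threat_features"))
  out <- numeric(nrow(features))
  for (i in seq_len(nrow(features))) {
    spec <- registry_lookup(registry, features$threat[i], features$category[i])
    out[i] <- if (spec$distance_rule == "plant_size") {
      ref <- registry[registry$threat == spec$threat &
                        registry$distance_rule == "plant_size", ]
      spec$distance_m * spec$magnitude / max(ref$magnitude)
    } else spec$distance_m
  }
  out
}

#' Build a threat feature collection
#'
#' @param threat,category Character vectors naming each feature's registry
#'   key.
#' @param geometry A list of [geom()] objects, one per feature.
#' @param attribute Optional numeric attribute (population density, water
#'   volume m3, ...) for attribute-scaled categories; NA elsewhere.
#' @param registry Registry used to validate keys (default shipped registry);
#'   `NULL` skips validation.
#' @return A data frame of class `threat_features` with a `geometry` list
#'   column.
#' @export
threat_features <- function(threat, category, geometry,
                            attribute = NA_real_,
                            registry = default_threat_registry()) {
  n <- length(geometry)
  stopifnot(length(threat) == n, length(category) == n,
            all(vapply(geometry, inherits, TRUE, "geom")))
  out <- data.frame(threat = as.character(threat),
                    category = as.character(category),
                    attribute = rep_len(as.numeric(attribute), n),
                    stringsAsFactors = FALSE)
  out$geometry <- geometry
  class(out) <- c("threat_features", "data.frame")
  if (!is.null(registry))
    for (i in seq_len(n)) registry_lookup(registry, out$threat[i], out$category[i])
  out
}

#' @export
print.threat_features <- function(x, ...) {
  cat(sprintf("threat_features: %d features across %d threat(s)\n",
              nrow(x), length(unique(x$threat))))
  if (nrow(x)) print(table(x$threat, dnn = NULL))
  invisible(x)
}
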