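# Pipeline orchestration: the four modeling scenarios, config validation,
# and a file-based CLI with seeded, manifest-logged stages.
#
# Scenarios: (a) local EII ~ threats, (b) local EII ~ threats + environment,
# (c) microbasin EII ~ threats, (d) microbasin EII ~ threats + environment.

scenario_info <- function(scenario) {
  switch(scenario,
    a = list(scale = "local", env = FALSE, max_terms = 7),
    b = list(scale = "local", env = TRUE, max_terms = 7),
    c = list(scale = "regional", env = FALSE, max_terms = 2),
    d = list(scale = "regional", env = TRUE, max_terms = 2),
    stop("scenario must be one of a, b, c, d", call. = FALSE))
}

#' Run one modeling scenario end to end
#'
#' From surfaces and scored sites to a coefficient report: assemble the
#' analysis table at the scenario's scale (pixel values at sites, or zonal
#' means per microbasin), min-max scale all predictors to \[0, 1\],
#' all-subsets AICc selection with collinearity screening, repeated k-fold
#' cross-validation of the best model, and projection onto the full grid
#' (local) or microbasin set (regional).
#'
#' @param sites Data frame with `site_id`, `x`, `y`, `eii`.
#' @param surfaces Named list of the nine threat `impact_surface`s.
#' @param env Named list with `elevation` and `slope` surfaces (needed for
#'   scenarios b and d).
#' @param scenario One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param basins A `microbasins` object (scenarios c/d; default a 5 x 5
#'   rectangular tiling of the grid).
#' @param k,repeats,cv_seed Cross-validation controls (defaults 7, 20).
#' @param collinearity_r Collinearity exclusion threshold (default 0.7).
#' @param predict Also project the best model (default TRUE).
#' @return A list of class `scenario_report`: `scenario`, `scale`, `n`,
#'   `selection` (full AICc table inside), `cv`, `fit`, `report` (Table-2
#'   style data frame: term, coefficient, SE, p, significance), `scaling`,
#'   and `prediction` (surface for local, basin table for regional) with
#'   clamp counts.
#' @export
run_scenario <- function(sites, surfaces, env = NULL,
                         scenario = c("a", "b", "c", "d"), basins = NULL,
                         k = 7, repeats = 20, cv_seed = 1,
                         collinearity_r = 0.7, predict = TRUE) {
  scenario <- match.arg(scenario)
  info <- scenario_info(scenario)
  if (info$env && is.null(env))
    stop("scenario ", scenario, " needs environmental rasters", call. = FALSE)
  layers <- surfaces
  if (info$env) layers <- c(surfaces, env)

  if (info$scale == "local") {
    raw <- data.frame(row.names = seq_len(nrow(sites)))
    for (nm in names(layers))
      raw[[nm]] <- sample_surface(layers[[nm]], sites$x, sites$y)
    y <- sites$eii
  } else {
    if (is.null(basins)) basins <- tile_microbasins(surfaces[[1]]$grid, 5, 5)
    membership <- assign_sites_to_microbasins(sites, basins)
    agg <- aggregate_microbasins(sites, layers, basins, membership)
    sampled <- !is.na(agg$eii)
    raw <- agg[sampled, names(layers), drop = FALSE]
    y <- agg$eii[sampled]
    agg_all <- agg
  }
  sc <- suppressWarnings(scale_predictors(raw))
  # threats with no features give all-zero surfaces; they carry no
  # information at this scale and are excluded from the candidate set
  informative <- vapply(sc$scaled, function(v) stats::var(v) > 0, TRUE)
  sel <- select_best(y, sc$scaled[informative], max_terms = info$max_terms,
                     collinearity_r = collinearity_r)
  cv <- cross_validate(y, sc$scaled, sel$best_terms, k = k,
                       repeats = repeats, seed = cv_seed)
  fit <- sel$best
  stars <- function(p) ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  report <- data.frame(term = names(fit$coefficients),
                       coefficient = unname(fit$coefficients),
                       se = unname(fit$se), p = unname(fit$p_values),
                       significance = stars(unname(fit$p_values)),
                       stringsAsFactors = FALSE)
  prediction <- NULL
  if (predict) {
    if (info$scale == "local") {
      prediction <- predict_surface(fit, layers, sc$record)
    } else {
      newdata <- apply_scaling(sc$record, agg_all[names(layers)])
      pred <- predict_ols(fit, newdata)
      clamped <- sum(pred < 0 | pred > 1)
      agg_all$predicted_eii <- pmin(1, pmax(0, pred))
      prediction <- structure(agg_all, n_clamped = clamped)
    }
  }
  structure(list(scenario = scenario, scale = info$scale, n = length(y),
                 selection = sel, cv = cv, fit = fit, report = report,
                 scaling = sc$record, prediction = prediction),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("scenario %s (%s scale, n = %d): best = {%s}\n",
              x$scenario, x$scale, x$n,
              if (length(x$selection$best_terms))
                paste(x$selection$best_terms, collapse = ", ")
              else "intercept"))
  print(transform(x$report, coefficient = round(coefficient, 3),
                  se = round(se, 3), p = signif(p, 2)))
  cat(sprintf("mean R2 (cross-validation) = %.2f (SD %.2f)\n",
              x$cv$mean_r2, x$cv$sd_r2))
  invisible(x)
}

#' Default pipeline configuration
#'
#' @return A nested list mirroring the shipped
#'   `inst/extdata/default_config.json`: grid, site count, feature counts,
#'   generating model, scenario, selection/CV parameters, seeds.
#' @export
default_pipeline_config <- function() {
  cfg <- synthetic_config()
  list(
    grid = list(origin_x = cfg$grid$origin_x, origin_y = cfg$grid$origin_y,
                pixel_size = cfg$grid$pixel_size, ncol = cfg$grid$ncol,
                nrow = cfg$grid$nrow, crs_note = cfg$grid$crs_note),
    n_sites = cfg$n_sites,
    feature_counts = as.list(cfg$feature_counts),
    beta0 = cfg$beta0, beta = as.list(cfg$beta),
    sigma = NULL, target_r2 = cfg$target_r2,
    scenario = "b",
    microbasins = list(nx = 5, ny = 5),
    selection = list(collinearity_r = 0.7),
    cv = list(k = 7, repeats = 20),
    seeds = list(simulation = cfg$seed, cv = 1),
    paths = list())
}

#' Validate a pipeline configuration
#'
#' Checks ranges, enums, seeds and referenced paths, aggregating all
#' problems rather than failing on the first; registry files named in
#' `paths$registry` are cross-checked against the shipped default threats.
#'
#' @param config A config list (see [default_pipeline_config()]) or a path
#'   to a JSON config file.
#' @return A list with `ok` (logical) and `errors` (character vector).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  errors <- character(0)
  err <- function(...) errors <<- c(errors, sprintf(...))
  g <- config$grid
  if (is.null(g)) err("missing grid spec") else {
    if (!is.numeric(g$pixel_size) || g$pixel_size <= 0)
      err("grid pixel_size must be > 0 (got %s)", format(g$pixel_size))
    if (is.null(g$ncol) || g$ncol < 2 || is.null(g$nrow) || g$nrow < 2)
      err("grid needs at least 2 pixels per axis")
  }
  if (!is.null(config$n_sites) && config$n_sites < 2)
    err("n_sites must be >= 2")
  if (!is.null(config$scenario) &&
      !all(config$scenario %in% c("a", "b", "c", "d")))
    err("unknown scenario '%s'", paste(config$scenario, collapse = ","))
  if (!is.null(config$sigma) && config$sigma < 0) err("sigma must be >= 0")
  for (s in names(config$seeds))
    if (config$seeds[[s]] != round(config$seeds[[s]]))
      err("seed '%s' is not an integer", s)
  if (!is.null(config$cv)) {
    if (config$cv$k < 2) err("cv k must be >= 2")
    if (config$cv$repeats < 1) err("cv repeats must be >= 1")
  }
  cr <- config$selection$collinearity_r
  if (!is.null(cr) && (cr <= 0 || cr > 1))
    err("collinearity_r must lie in (0, 1]")
  fc <- config$feature_counts
  if (!is.null(fc)) {
    known <- unique(default_threat_registry()$threat)
    for (t in setdiff(sub("/.*$", "", names(fc)), known))
      err("unknown threat '%s'", t)
    if (any(unlist(fc) < 0)) err("feature counts must be >= 0")
  }
  for (p in names(config$paths)) {
    path <- config$paths[[p]]
    if (!is.null(path) && !file.exists(path))
      err("path '%s' does not exist: %s", p, path)
  }
  if (!is.null(config$paths$registry) && file.exists(config$paths$registry)) {
    reg <- tryCatch(read_threat_registry(config$paths$registry),
                    error = function(e) {
                      err("registry unreadable: %s", conditionMessage(e))
                      NULL
                    })
    if (!is.null(reg)) {
      extra <- setdiff(unique(reg$threat),
                       unique(default_threat_registry()$threat))
      for (t in extra) err("registry threat '%s' is not a known threat", t)
    }
  }
  list(ok = length(errors) == 0L, errors = errors)
}

#' Read / write a pipeline config (JSON)
#'
#' @param path JSON file path.
#' @return `read_pipeline_config` returns the config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$beta)) cfg$beta <- unlist(cfg$beta)
  if (!is.null(cfg$feature_counts))
    cfg$feature_counts <- unlist(cfg$feature_counts)
  cfg
}

#' @rdname read_pipeline_config
#' @param config Config list.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

config_to_synthetic <- function(config) {
  g <- config$grid
  synthetic_config(
    grid = grid_spec(g$origin_x, g$origin_y, g$pixel_size, g$ncol, g$nrow,
                     crs_note = if (is.null(g$crs_note)) "local planar (m)"
                                else g$crs_note),
    n_sites = config$n_sites,
    feature_counts = unlist(config$feature_counts),
    beta0 = config$beta0, beta = unlist(config$beta),
    sigma = config$sigma, target_r2 = config$target_r2,
    seed = config$seeds$simulation)
}

#' Write a synthetic landscape to disk as standard formats
#'
#' GeoJSON features, one `.asc` raster per threat plus elevation and slope,
#' a CSV site table, and a JSON record of the generating model.
#'
#' @param landscape A `synthetic_landscape`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of files written.
#' @export
write_landscape <- function(landscape, out_dir) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(features = file.path(out_dir, "features.geojson"),
             sites = file.path(out_dir, "sites.csv"),
             truth = file.path(out_dir, "true_model.json"))
  write_features_geojson(landscape$features, files[["features"]])
  utils::write.csv(landscape$sites, files[["sites"]], row.names = FALSE)
  jsonlite::write_json(list(beta0 = landscape$beta0,
                            beta = as.list(landscape$beta),
                            sigma = landscape$sigma,
                            n_clamped = landscape$n_clamped,
                            seed = landscape$config$seed),
                       files[["truth"]], auto_unbox = TRUE, digits = NA)
  for (nm in names(landscape$surfaces)) {
    f <- file.path(out_dir, paste0("threat_", nm, ".asc"))
    write_asc(landscape$surfaces[[nm]], f)
    files[[paste0("threat_", nm)]] <- f
  }
  for (nm in names(landscape$env)) {
    f <- file.path(out_dir, paste0(nm, ".asc"))
    write_asc(landscape$env[[nm]], f)
    files[[nm]] <- f
  }
  invisible(files)
}

#' Read surfaces written by [write_landscape()] back from a directory
#'
#' @param dir Directory containing `threat_*.asc`, `elevation.asc`,
#'   `slope.asc` and `sites.csv`.
#' @return A list with `surfaces`, `env`, `sites`.
#' @export
read_landscape_dir <- function(dir) {
  tf <- list.files(dir, pattern = "^threat_.*\\.asc$", full.names = TRUE)
  surfaces <- lapply(tf, read_asc)
  names(surfaces) <- sub("^threat_", "", sub("\\.asc$", "", basename(tf)))
  env <- list()
  for (nm in c("elevation", "slope")) {
    f <- file.path(dir, paste0(nm, ".asc"))
    if (file.exists(f)) env[[nm]] <- read_asc(f)
  }
  sites <- NULL
  f <- file.path(dir, "sites.csv")
  if (file.exists(f)) sites <- utils::read.csv(f, stringsAsFactors = FALSE)
  list(surfaces = surfaces, env = env, sites = sites)
}

write_manifest <- function(out_dir, config, files, warnings = character(0)) {
  manifest <- list(
    package = "ecointegrity",
    version = as.character(utils::packageVersion("ecointegrity")),
    config = config,
    seeds = config$seeds,
    checksums = as.list(tools::md5sum(unname(unlist(files)))),
    warnings = warnings)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Command-line pipeline driver
#'
#' Subcommands (first element of `argv`): `simulate`, `build-threats`,
#' `eii`, `moran`, `aggregate`, `model`, `cv`, `predict`, `run-all`,
#' `validate`. Remaining arguments: `--config <path>` (JSON),
#' `--out <dir>`, and for stage commands `--in <dir>` (a directory written
#' by an earlier stage). Run via
#' `Rscript -e 'ecointegrity::pipeline_cli()' <subcommand> ...`.
#'
#' @param argv Character vector of arguments (defaults to the command
#'   line).
#' @return Exit status, invisibly: 0 success, 2 validation failure.
#'   Runtime failures raise errors (exit 1 under `Rscript`).
#' @export
pipeline_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    message("usage: pipeline_cli <simulate|build-threats|eii|moran|aggregate|",
            "model|cv|predict|run-all|validate> [--config F] [--in D] [--out D]")
    return(invisible(2L))
  }
  cmd <- argv[1]
  opts <- parse_cli_opts(argv[-1])
  config <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
            else default_pipeline_config()
  v <- validate_config(config)
  if (!v$ok) {
    for (e in v$errors) message("config error: ", e)
    return(invisible(2L))
  }
  if (cmd == "validate") {
    message("config OK")
    return(invisible(0L))
  }
  out <- if (!is.null(opts$out)) opts$out else "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  indir <- if (!is.null(opts$`in`)) opts$`in` else out

  if (cmd == "simulate") {
    ls <- generate_landscape(config_to_synthetic(config))
    files <- write_landscape(ls, out)
    write_manifest(out, config, files,
                   warnings = if (ls$n_clamped)
                     sprintf("%d simulated EII values clamped", ls$n_clamped)
                   else character(0))
    message(sprintf("simulate: %d sites, %d features -> %s",
                    nrow(ls$sites), nrow(ls$features), out))
    return(invisible(0L))
  }

  if (cmd == "build-threats") {
    feats <- read_features_geojson(file.path(indir, "features.geojson"))
    g <- grid_spec(config$grid$origin_x, config$grid$origin_y,
                   config$grid$pixel_size, config$grid$ncol, config$grid$nrow)
    surfaces <- build_threat_surfaces(feats, grid = g)
    for (nm in names(surfaces))
      write_asc(surfaces[[nm]], file.path(out, paste0("threat_", nm, ".asc")))
    message(sprintf("build-threats: %d features -> %d surfaces",
                    nrow(feats), length(surfaces)))
    return(invisible(0L))
  }

  if (cmd == "eii") {
    sites <- utils::read.csv(file.path(indir, "sites.csv"),
                             stringsAsFactors = FALSE)
    taxa <- utils::read.csv(file.path(indir, "taxa.csv"),
                            stringsAsFactors = FALSE)
    tol <- if (!is.null(config$paths$tolerance))
      utils::read.csv(config$paths$tolerance, stringsAsFactors = FALSE)
    else synthetic_tolerance_table()
    scored <- score_sites(sites, taxa, tol)
    utils::write.csv(scored, file.path(out, "eii.csv"), row.names = FALSE)
    message(sprintf("eii: scored %d sites", nrow(scored)))
    return(invisible(0L))
  }

  dat <- read_landscape_dir(indir)
  if (cmd == "moran") {
    w <- inverse_distance_weights(cbind(dat$sites$x, dat$sites$y))
    m <- morans_i(dat$sites$eii, w)
    jsonlite::write_json(m[c("I", "expected", "variance", "z", "p", "n")],
                         file.path(out, "moran.json"), auto_unbox = TRUE,
                         digits = NA)
    message(sprintf("moran: I = %.4f, Z = %.2f", m$I, m$z))
    return(invisible(0L))
  }
  if (cmd == "aggregate") {
    basins <- if (!is.null(config$paths$microbasins))
      read_microbasins_geojson(config$paths$microbasins)
    else tile_microbasins(dat$surfaces[[1]]$grid,
                          config$microbasins$nx, config$microbasins$ny)
    membership <- assign_sites_to_microbasins(dat$sites, basins)
    agg <- aggregate_microbasins(dat$sites, c(dat$surfaces, dat$env),
                                 basins, membership)
    utils::write.csv(agg, file.path(out, "microbasins.csv"),
                     row.names = FALSE)
    message(sprintf("aggregate: %d basins, %d with sites", nrow(agg),
                    sum(agg$n_sites > 0)))
    return(invisible(0L))
  }
  if (cmd %in% c("model", "cv", "predict", "run-all")) {
    scen <- if (!is.null(config$scenario)) config$scenario else "b"
    for (s in scen) {
      rep <- run_scenario(dat$sites, dat$surfaces, dat$env, scenario = s,
                          k = config$cv$k, repeats = config$cv$repeats,
                          cv_seed = config$seeds$cv,
                          collinearity_r = config$selection$collinearity_r,
                          predict = cmd %in% c("predict", "run-all"))
      stem <- file.path(out, paste0("scenario_", s))
      utils::write.csv(rep$selection$table, paste0(stem, "_aicc_table.csv"),
                       row.names = FALSE)
      utils::write.csv(rep$report, paste0(stem, "_coefficients.csv"),
                       row.names = FALSE)
      jsonlite::write_json(list(scenario = s, n = rep$n,
                                terms = rep$selection$best_terms,
                                mean_r2 = rep$cv$mean_r2,
                                sd_r2 = rep$cv$sd_r2,
                                k = rep$cv$k, repeats = rep$cv$repeats),
                           paste0(stem, "_cv.json"), auto_unbox = TRUE,
                           digits = NA)
      if (!is.null(rep$prediction)) {
        if (rep$scale == "local")
          write_asc(rep$prediction, paste0(stem, "_predicted_eii.asc"))
        else
          utils::write.csv(as.data.frame(rep$prediction),
                           paste0(stem, "_predicted_eii.csv"),
                           row.names = FALSE)
      }
      message(sprintf("scenario %s: best {%s}, mean R2 = %.3f", s,
                      paste(rep$selection$best_terms, collapse = ", "),
                      rep$cv$mean_r2))
    }
    return(invisible(0L))
  }
  stop("unknown subcommand: ", cmd, call. = FALSE)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      opts[[substring(a, 3)]] <- args[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  opts
}
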