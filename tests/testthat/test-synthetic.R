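test_that("environmental rasters: flat and planar closed forms, determinism", {
  # flat elevation -> slope 0 everywhere
  expect_equal(slope_from_elevation(matrix(500, 8, 8), 500),
               matrix(0, 8, 8))
  # planar gradient g per pixel -> uniform slope atan(g / pixel)
  g <- 25
  elev <- outer(rep(0, 6), (0:5) * g, `+`)
  expect_equal(slope_from_elevation(elev, 500),
               matrix(atan(g / 500) * 180 / pi, 6, 6))
  expect_error(slope_from_elevation(matrix(1, 1, 5), 500), "at least 2")
  gs <- grid_spec(0, 0, 500, 20, 20)
  a <- generate_env_rasters(gs, seed = 3)
  b <- generate_env_rasters(gs, seed = 3)
  expect_identical(a$elevation$values, b$elevation$values)
  expect_identical(a$slope$values, b$slope$values)
  expect_true(all(is.finite(a$elevation$values)))
  expect_true(all(is.finite(a$slope$values)))
  # slope is consistent with central differences on the elevation field
  e <- a$elevation$values
  i <- 10; j <- 10
  dzdx <- (e[i, j + 1] - e[i, j - 1]) / 1000
  dzdy <- (e[i + 1, j] - e[i - 1, j]) / 1000
  expect_equal(a$slope$values[i, j],
               atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi)
})

test_that("threat feature generation is seeded, in-extent and registry-valid", {
  cfg <- synthetic_config(seed = 13)
  f1 <- generate_threat_features(cfg)
  f2 <- generate_threat_features(cfg)
  expect_equal(nrow(f1), sum(cfg$feature_counts))
  for (i in seq_len(nrow(f1)))
    expect_equal(f1$geometry[[i]]$coords, f2$geometry[[i]]$coords)
  expect_identical(f1$category, f2$category)
  reg <- default_threat_registry()
  key <- paste(f1$threat, f1$category)
  expect_true(all(key %in% paste(reg$threat, reg$category)))
  g <- cfg$grid
  for (i in seq_len(nrow(f1))) {
    cc <- f1$geometry[[i]]$coords
    expect_true(all(cc[, 1] >= g$origin_x &
                      cc[, 1] <= g$origin_x + g$ncol * g$pixel_size))
    expect_true(all(cc[, 2] >= g$origin_y &
                      cc[, 2] <= g$origin_y + g$nrow * g$pixel_size))
  }
  # attribute-scaled categories carry attributes
  att_rows <- f1$threat %in% c("aquaculture", "water_withdrawals")
  expect_true(all(!is.na(f1$attribute[att_rows])))
  # zero counts -> empty collection
  cfg0 <- synthetic_config(feature_counts = c(roads = 0), seed = 1)
  expect_equal(nrow(generate_threat_features(cfg0)), 0)
  # count request honored per threat/category label
  cfg5 <- synthetic_config(feature_counts = c(human_settlements = 5), seed = 2)
  f5 <- generate_threat_features(cfg5)
  expect_equal(nrow(f5), 5)
  expect_true(all(f5$threat == "human_settlements" &
                    f5$category %in% c("urban_area", "village")))
})

test_that("simulate_eii reproduces the linear model exactly at sigma = 0", {
  pred <- data.frame(x = c(0.4, 0, 1))
  out <- simulate_eii(pred, beta0 = 0.8, beta = c(x = -0.5), sigma = 0,
                      seed = 1)
  expect_equal(out$eii, c(0.6, 0.8, 0.3))
  out2 <- simulate_eii(pred, beta0 = 0.55, beta = c(x = 0), sigma = 0)
  expect_equal(out2$eii, rep(0.55, 3))
  expect_error(simulate_eii(pred, 0.8, c(zz = 1), 0), "missing")
  expect_error(simulate_eii(data.frame(x = c(2, 3)), 0.8, c(x = 1), 0),
               "scaled")
  # sigma = 0 and n sites: OLS recovers (beta0, beta) to machine precision
  set.seed(71)
  X <- data.frame(a = runif(60), b = runif(60))
  sim <- simulate_eii(X, 0.6, c(a = -0.2, b = 0.1), sigma = 0)
  f <- fit_ols(sim$eii, X)
  expect_equal(unname(f$coefficients), c(0.6, -0.2, 0.1), tolerance = 1e-12)
})

test_that("analytic R2 calibration: OLS R2 matches the target at n = 10,000", {
  set.seed(72)
  n <- 10000
  x <- runif(n)
  beta <- c(x = -0.4)
  signal <- 0.8 - 0.4 * x
  for (target in c(0.25, 0.5)) {
    sigma <- sd(signal) * sqrt((1 - target) / target)
    sim <- simulate_eii(data.frame(x = x), 0.8, beta, sigma, seed = 73)
    f <- fit_ols(sim$eii, data.frame(x = x))
    expect_lt(abs(f$r2 - target), 0.02)
  }
})

test_that("landscape generation is deterministic and in-spec", {
  cfg <- synthetic_config(seed = 14)
  l1 <- generate_landscape(cfg)
  l2 <- generate_landscape(cfg)
  expect_identical(l1$sites, l2$sites)
  expect_identical(l1$predictors, l2$predictors)
  expect_equal(l1$sigma, l2$sigma)
  # serialized forms are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  write_landscape(l1, d1); write_landscape(l2, d2)
  for (f in c("sites.csv", "features.geojson", "threat_roads.asc",
              "elevation.asc", "true_model.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_equal(nrow(l1$sites), 140)
  expect_length(l1$surfaces, 9)
  expect_true(all(l1$sites$eii >= 0 & l1$sites$eii <= 1))
  g <- cfg$grid
  expect_true(all(l1$sites$x >= g$origin_x &
                    l1$sites$x <= g$origin_x + g$ncol * g$pixel_size))
  # predictors handed to the generating model are on [0, 1]
  expect_true(all(as.matrix(l1$predictors) >= 0 &
                    as.matrix(l1$predictors) <= 1))
})

test_that("clamping is rare with the default configuration", {
  clamped <- vapply(1:10, function(s)
    generate_landscape(synthetic_config(seed = s))$n_clamped, 0)
  expect_lt(mean(clamped) / 140, 0.01)
})

test_that("simulated site parameters round-trip through the scoring pipeline", {
  set.seed(74)
  targets <- data.frame(biotic = runif(20), habitat = runif(20),
                        physchem = runif(20))
  sim <- simulate_site_parameters(targets, seed = 4)
  got <- do.call(score_sites,
                 c(list(sites = sim$sites, taxa = sim$taxa),
                   sim$scoring_args))
  expect_lt(max(abs(got$biotic - targets$biotic)), 0.02)
  expect_lt(max(abs(got$habitat - targets$habitat)), 0.02)
  expect_lt(max(abs(got$physchem - targets$physchem)), 0.02)
  # boundary targets: score-1.0 biotic uses only maximum-tolerance families
  simb <- simulate_site_parameters(
    data.frame(biotic = 1, habitat = 0.5, physchem = 1), seed = 5)
  tab <- as.data.frame(synthetic_tolerance_table())
  picked <- tab$score[match(simb$taxa$family, tab$family)]
  expect_true(all(picked == 10))
  expect_equal(simb$sites$qbr, 50)
  # infeasible: tiny table cannot host the requested richness at the extremes
  expect_error(simulate_site_parameters(
    targets[1, ], tolerance_table = data.frame(family = c("a", "b"),
                                               score = c(1, 10))),
    "infeasible")
})
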