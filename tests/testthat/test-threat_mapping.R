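reg <- default_threat_registry()

test_that("registry resolves fixed magnitudes and distances verbatim", {
  f <- threat_features(
    c("human_settlements", "human_settlements", "oil", "oil"),
    c("urban_area", "village", "pipeline_risky", "pipeline_out_of_risk"),
    list(geom("point", cbind(0, 0)), geom("point", cbind(1, 1)),
         geom("line", cbind(c(0, 1), c(0, 1))),
         geom("line", cbind(c(2, 3), c(2, 3)))))
  expect_equal(resolve_magnitude(f, reg), c(0.65, 0.35, 0.07, 0.03))
  expect_equal(resolve_distance(f, reg), c(10000, 3000, 30, 30))
})

test_that("attribute scaling maps observed volume range onto [0.1, 1]", {
  f <- threat_features(rep("aquaculture", 3), rep("farm", 3),
                       list(geom("point", cbind(0, 0)),
                            geom("point", cbind(1, 0)),
                            geom("point", cbind(2, 0))),
                       attribute = c(500, 10250, 20000))
  expect_equal(resolve_magnitude(f, reg), c(0.1, 0.55, 1.0))
  # missing attribute errors
  f2 <- threat_features("aquaculture", "farm",
                        list(geom("point", cbind(0, 0))))
  expect_error(resolve_magnitude(f2, reg), "attribute")
})

test_that("hydroelectric impact distance scales with plant size, capped at 30 km", {
  cats <- c("operating_large", "operating_medium", "operating_small",
            "construction_large", "construction_medium", "construction_small")
  f <- threat_features(rep("hydroelectric", 6), cats,
                       replicate(6, geom("point", cbind(0, 0)),
                                 simplify = FALSE))
  expect_equal(resolve_distance(f, reg),
               30000 * c(0.375, 0.225, 0.15, 0.125, 0.075, 0.05) / 0.375)
})

test_that("unknown threat/category keys are rejected", {
  expect_error(threat_features("piracy", "ships",
                               list(geom("point", cbind(0, 0)))),
               "not in registry")
  expect_error(threat_features("oil", "fracking",
                               list(geom("point", cbind(0, 0)))),
               "not in registry")
})

test_that("linear decay: full at source, half at midpoint, zero at the edge", {
  expect_equal(decayed_impact(0.65, 0, 10000), 0.65)
  expect_equal(decayed_impact(0.65, 5000, 10000), 0.325)
  expect_equal(decayed_impact(0.35, 3000, 3000), 0)
  expect_equal(decayed_impact(0.5, 99999, 1000), 0)
  expect_error(decayed_impact(0.5, 100, 0), "max_distance")
})

test_that("registry file round-trips losslessly", {
  shipped <- system.file("extdata", "threat_registry.csv",
                         package = "ecointegrity")
  expect_identical(as.data.frame(read_threat_registry(shipped)),
                   as.data.frame(reg))
  tmp <- tempfile(fileext = ".csv")
  write_threat_registry(reg, tmp)
  expect_identical(as.data.frame(read_threat_registry(tmp)),
                   as.data.frame(reg))
})

test_that("a village point at a pixel center rasterizes to 0.35, zero beyond 3 km", {
  g <- grid_spec(0, 0, 500, 20, 20)
  ctr <- pixel_centers(g)
  f <- threat_features("human_settlements", "village",
                       list(geom("point", cbind(250, 250))))
  s <- rasterize_threat(f, reg, g)
  expect_equal(s$values[1, 1], 0.35)
  far <- sqrt((ctr[, 1] - 250)^2 + (ctr[, 2] - 250)^2) >= 3000
  expect_true(all(s$values[far] == 0))
  expect_true(all(s$values >= 0 & s$values <= 1))
})

test_that("overlapping buffers add and the cap policy truncates at 1", {
  g <- grid_spec(0, 0, 500, 10, 10)
  f <- threat_features(rep("human_settlements", 2), rep("urban_area", 2),
                       list(geom("point", cbind(2250, 2250)),
                            geom("point", cbind(2250, 2250))))
  s <- rasterize_threat(f, reg, g)
  expect_equal(s$values[5, 5], 1.0)    # 0.65 + 0.65 capped
  s2 <- rasterize_threat(f, reg, g, policy = "rescale")
  expect_equal(max(s2$values), 1.0)
  expect_equal(s2$values[5, 5], 1.0)
})

test_that("rasterizer equals the brute-force per-pixel oracle on mixed features", {
  for (seed in 1:5) {
    g <- grid_spec(0, 0, 500, 15, 12)
    feats <- random_features(8, g, reg, seed = seed)
    for (t in unique(feats$threat)) {
      sub <- feats[feats$threat == t, ]
      class(sub) <- class(feats)
      s <- rasterize_threat(sub, reg, g)
      expect_equal(s$values, oracle_rasterize(sub, reg, g),
                   tolerance = 1e-12)
    }
  }
})

test_that("single-feature impact is non-increasing with distance", {
  g <- grid_spec(0, 0, 500, 30, 30)
  f <- threat_features("mining", "metal",
                       list(geom("point", cbind(7250, 7250))))
  s <- rasterize_threat(f, reg, g)
  ctr <- pixel_centers(g)
  d <- sqrt((ctr[, 1] - 7250)^2 + (ctr[, 2] - 7250)^2)
  ord <- order(d)
  expect_true(all(diff(as.vector(s$values)[ord]) <= 1e-12))
})

test_that("superposition holds below the cap", {
  g <- grid_spec(0, 0, 500, 20, 20)
  fa <- threat_features("oil", "well_operating",
                        list(geom("point", cbind(2000, 2000))))
  fb <- threat_features("oil", "spill_old_low",
                        list(geom("point", cbind(6000, 6000))))
  fab <- threat_features(c("oil", "oil"),
                         c("well_operating", "spill_old_low"),
                         c(fa$geometry, fb$geometry))
  sa <- rasterize_threat(fa, reg, g)$values
  sb <- rasterize_threat(fb, reg, g)$values
  expect_true(max(sa + sb) <= 1)  # precondition of the property
  expect_equal(rasterize_threat(fab, reg, g)$values, sa + sb)
})

test_that("polygon interiors receive the full magnitude (d = 0)", {
  g <- grid_spec(0, 0, 500, 10, 10)
  f <- threat_features("agriculture", "crops",
                       list(geom("polygon", rbind(c(1000, 1000), c(4000, 1000),
                                                  c(4000, 4000), c(1000, 4000)))))
  s <- rasterize_threat(f, reg, g)
  expect_equal(s$values[5, 5], 0.6)   # center (2250,2250) inside
})

test_that("sample_surface does point-in-pixel lookup, errors outside the grid", {
  g <- grid_spec(0, 0, 500, 12, 9)
  vals <- matrix(runif(12 * 9), 9, 12)
  s <- impact_surface(vals, g)
  set.seed(11)
  x <- runif(100, 0, 6000); y <- runif(100, 0, 4500)
  got <- sample_surface(s, x, y)
  manual <- vapply(seq_along(x), function(i) {
    vals[min(9, floor(y[i] / 500) + 1), min(12, floor(x[i] / 500) + 1)]
  }, 0)
  expect_equal(got, manual)
  expect_equal(sample_surface(s, 250, 250), vals[1, 1])
  expect_error(sample_surface(s, -10, 200), "outside")
})

test_that("surface extent fraction counts pixels above threshold", {
  g <- grid_spec(0, 0, 500, 10, 10)
  z <- impact_surface(matrix(0, 10, 10), g)
  expect_equal(surface_extent_fraction(z), 0)
  half <- matrix(c(rep(0.2, 50), rep(0, 50)), 10, 10)
  expect_equal(surface_extent_fraction(impact_surface(half, g)), 0.5)
  set.seed(3)
  r <- matrix(runif(100), 10, 10)
  expect_equal(surface_extent_fraction(impact_surface(r, g), 0.7),
               sum(r > 0.7) / 100)
})

test_that("ascii grid and GeoJSON round-trips preserve data", {
  g <- grid_spec(1000, 2000, 250, 8, 6)
  set.seed(5)
  s <- impact_surface(matrix(runif(48), 6, 8), g, name = "roads")
  tmp <- tempfile(fileext = ".asc")
  write_asc(s, tmp)
  s2 <- read_asc(tmp)
  expect_equal(s2$values, s$values)
  expect_equal(s2$grid$pixel_size, 250)
  expect_equal(s2$grid$origin_x, 1000)

  feats <- random_features(6, g, reg, seed = 2)
  tmpj <- tempfile(fileext = ".geojson")
  write_features_geojson(feats, tmpj)
  feats2 <- read_features_geojson(tmpj)
  expect_equal(feats2$threat, feats$threat)
  expect_equal(feats2$category, feats$category)
  expect_equal(feats2$attribute, feats$attribute)
  for (i in seq_len(nrow(feats)))
    expect_equal(feats2$geometry[[i]]$coords, feats$geometry[[i]]$coords)
})

test_that("build_threat_surfaces yields one surface per registry threat", {
  g <- grid_spec(0, 0, 500, 10, 10)
  f <- threat_features("roads", "primary",
                       list(geom("line", cbind(c(0, 5000), c(2500, 2500)))))
  out <- build_threat_surfaces(f, reg, g)
  expect_setequal(names(out), unique(reg$threat))
  expect_true(max(out$roads$values) > 0)
  expect_true(all(out$mining$values == 0))
})
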