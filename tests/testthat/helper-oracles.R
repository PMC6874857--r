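# Independent oracle implementations used across the suite. These
# deliberately avoid the package's internal code paths: brute-force loops,
# closed forms and textbook formulas only.

# distance from one point to one geometry, scalar brute force
oracle_point_geom_distance <- function(x, y, g) {
  seg_dist <- function(p, a, b) {
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) return(sqrt(sum((p - a)^2)))
    t <- max(0, min(1, sum((p - a) * ab) / len2))
    sqrt(sum((p - (a + t * ab))^2))
  }
  cc <- g$coords
  if (g$type == "point") return(sqrt((x - cc[1, 1])^2 + (y - cc[1, 2])^2))
  n <- nrow(cc)
  pairs <- if (g$type == "line") cbind(1:(n - 1), 2:n) else
    cbind(seq_len(n), c(2:n, 1))
  d <- min(apply(pairs, 1, function(ij)
    seg_dist(c(x, y), cc[ij[1], ], cc[ij[2], ])))
  if (g$type == "polygon" && oracle_point_in_polygon(x, y, cc)) d <- 0
  d
}

# winding-number point-in-polygon (different algorithm from the package's
# even-odd crossing test)
oracle_point_in_polygon <- function(x, y, coords) {
  n <- nrow(coords)
  wn <- 0
  for (i in seq_len(n)) {
    a <- coords[i, ]; b <- coords[if (i == n) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (y - a[2]) - (x - a[1]) * (b[2] - a[2])
    # boundary points: treat as inside
    if (cross == 0 &&
        x >= min(a[1], b[1]) - 1e-12 && x <= max(a[1], b[1]) + 1e-12 &&
        y >= min(a[2], b[2]) - 1e-12 && y <= max(a[2], b[2]) + 1e-12) {
      onseg <- abs((b[1] - a[1]) * (y - a[2]) - (x - a[1]) * (b[2] - a[2]))
      if (onseg < 1e-9) return(TRUE)
    }
    if (a[2] <= y) {
      if (b[2] > y && cross > 0) wn <- wn + 1
    } else {
      if (b[2] <= y && cross < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# brute-force threat rasterization: explicit per-pixel per-feature loop
oracle_rasterize <- function(features, registry, grid, cap = TRUE) {
  mags <- resolve_magnitude(features, registry)
  dists <- resolve_distance(features, registry)
  vals <- matrix(0, grid$nrow, grid$ncol)
  for (i in seq_len(grid$nrow)) for (j in seq_len(grid$ncol)) {
    cx <- grid$origin_x + (j - 0.5) * grid$pixel_size
    cy <- grid$origin_y + (i - 0.5) * grid$pixel_size
    tot <- 0
    for (f in seq_len(nrow(features))) {
      d <- oracle_point_geom_distance(cx, cy, features$geometry[[f]])
      if (d < dists[f]) tot <- tot + mags[f] * (1 - d / dists[f])
    }
    vals[i, j] <- if (cap) min(1, tot) else tot
  }
  vals
}

# textbook AICc
oracle_aicc <- function(loglik, n, k) {
  -2 * loglik + 2 * k + (2 * k * (k + 1)) / (n - k - 1)
}

# normal-equations OLS
oracle_ols_coefs <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))
}

# brute-force double-sum Moran's I
oracle_morans_i <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * z[i] * z[j]
  (n / sum(w)) * num / sum(z^2)
}

# random mixed feature set for rasterizer oracle tests
random_features <- function(n, grid, registry, seed) {
  set.seed(seed)
  xmax <- grid$origin_x + grid$ncol * grid$pixel_size
  ymax <- grid$origin_y + grid$nrow * grid$pixel_size
  rows <- registry[sample.int(nrow(registry), n, replace = TRUE), ]
  geometry <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- sample(c("point", "line", "polygon"), 1)
    if (kind == "point") {
      geometry[[i]] <- geom("point", cbind(runif(1, grid$origin_x, xmax),
                                           runif(1, grid$origin_y, ymax)))
    } else if (kind == "line") {
      geometry[[i]] <- geom("line", cbind(runif(3, grid$origin_x, xmax),
                                          runif(3, grid$origin_y, ymax)))
    } else {
      x0 <- runif(1, grid$origin_x, xmax - 1000)
      y0 <- runif(1, grid$origin_y, ymax - 1000)
      w <- runif(1, 200, 3000); h <- runif(1, 200, 3000)
      geometry[[i]] <- geom("polygon",
                            rbind(c(x0, y0), c(x0 + w, y0),
                                  c(x0 + w, y0 + h), c(x0, y0 + h)))
    }
  }
  att <- ifelse(rows$magnitude_rule == "attribute", runif(n, 1e3, 1e5),
                NA_real_)
  threat_features(rows$threat, rows$category, geometry, att,
                  registry = registry)
}
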