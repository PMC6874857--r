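test_that("predictor scaling maps to [0,1] and replays on new data", {
  sc <- scale_predictors(data.frame(a = c(2, 4, 6), b = c(0, 0.5, 1)))
  expect_equal(sc$scaled$a, c(0, 0.5, 1))
  expect_equal(sc$scaled$b, c(0, 0.5, 1))   # unchanged: min 0, max 1
  expect_equal(apply_scaling(sc$record, data.frame(a = 5, b = 0.25))$a, 0.75)
  expect_warning(scale_predictors(data.frame(k = c(3, 3))), "constant")
})

test_that("fit_ols recovers exact linear relationships and the intercept-only mean", {
  x <- seq(0, 1, length.out = 25)
  y <- 0.8 - 0.5 * x
  f <- fit_ols(y, data.frame(x = x))
  expect_equal(unname(f$coefficients), c(0.8, -0.5), tolerance = 1e-12)
  f0 <- fit_ols(y, data.frame()[seq_along(y), , drop = FALSE])
  expect_equal(unname(f0$coefficients), mean(y))
  expect_error(fit_ols(y, data.frame(x = x, x2 = 2 * x)), "collinear")
})

test_that("fit_ols equals the normal-equations oracle on random data", {
  set.seed(61)
  for (i in 1:10) {
    X <- data.frame(matrix(rnorm(60), 20, 3))
    y <- rnorm(20)
    f <- fit_ols(y, X)
    expect_equal(unname(f$coefficients), oracle_ols_coefs(y, X),
                 tolerance = 1e-9)
    # log-likelihood at the MLE variance
    rss <- sum((y - f$fitted)^2)
    expect_equal(f$loglik, sum(dnorm(y, f$fitted, sqrt(rss / 20), log = TRUE)))
  }
})

test_that("AICc matches the closed form and its large-n limit", {
  expect_equal(aicc(-10, 20, 3), 27.5)
  expect_equal(aicc(-10, 20, 19), Inf)  # n - k - 1 <= 0 inadmissible
  expect_lt(abs(aicc(-100, 1e6, 3) - (-2 * -100 + 2 * 3)), 1e-3)
  set.seed(62)
  for (i in 1:50) {
    ll <- runif(1, -200, -1); n <- sample(10:500, 1)
    k <- sample(2:(min(n - 2, 9)), 1)
    expect_equal(aicc(ll, n, k), oracle_aicc(ll, n, k))
  }
})

test_that("candidate enumeration respects size and collinearity limits", {
  cm5 <- diag(5); dimnames(cm5) <- list(letters[1:5], letters[1:5])
  cands <- enumerate_candidates(letters[1:5], cm5, max_terms = 2)
  expect_length(cands, 16)   # 1 + 5 + 10
  cm2 <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
                dimnames = list(c("x1", "x2"), c("x1", "x2")))
  expect_equal(enumerate_candidates(c("x1", "x2"), cm2, 2),
               list(character(0), "x1", "x2"))
  # random correlation structures vs a brute-force filter
  set.seed(63)
  for (i in 1:10) {
    p <- sample(3:6, 1)
    Z <- matrix(rnorm(40 * p), 40, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    Z[, p] <- Z[, 1] * 0.95 + rnorm(40, sd = 0.1)  # force a collinear pair
    cm <- cor(Z)
    got <- enumerate_candidates(colnames(Z), cm, max_terms = p)
    brute <- Filter(function(s) {
      if (length(s) < 2) return(TRUE)
      all(abs(cm[s, s][upper.tri(diag(length(s)))]) <= 0.7)
    }, unlist(lapply(0:p, function(k)
      utils::combn(colnames(Z), k, simplify = FALSE)), recursive = FALSE))
    expect_equal(lapply(got, sort), lapply(brute, sort))
  }
})

test_that("select_best finds the exact signal and agrees with exhaustive enumeration", {
  set.seed(64)
  n <- 50
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n),
                  x4 = runif(n), x5 = runif(n))
  y <- 0.7 - 0.4 * X$x1    # noiseless: only x1 carries signal
  sel <- select_best(y, X, max_terms = 3)
  expect_equal(sel$best_terms, "x1")
  # with noise: best AICc equals an independent refit of every candidate
  y2 <- y + rnorm(n, sd = 0.1)
  sel2 <- select_best(y2, X, max_terms = 3)
  cm <- cor(X)
  all_aicc <- vapply(enumerate_candidates(names(X), cm, 3), function(s) {
    X1 <- cbind(1, as.matrix(X[s]))
    co <- solve(t(X1) %*% X1, t(X1) %*% y2)
    rss <- sum((y2 - X1 %*% co)^2)
    ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    oracle_aicc(ll, n, length(s) + 2)
  }, 0)
  expect_equal(sel2$best$aicc, min(all_aicc))
  expect_equal(min(sel2$table$aicc), sel2$best$aicc)
  # no selected row pairs collinear predictors
  expect_true(all(sel2$table$n_terms <= 3))
})

test_that("pure-noise responses mostly select the intercept-only model", {
  set.seed(65)
  wins <- 0
  for (i in 1:20) {
    n <- 200
    X <- data.frame(a = runif(n), b = runif(n), c = runif(n))
    y <- rnorm(n)
    if (length(select_best(y, X, max_terms = 3)$best_terms) == 0)
      wins <- wins + 1
  }
  expect_gt(wins, 10)
})

test_that("r_squared conventions", {
  x <- c(1, 2, 3, 4)
  expect_equal(r_squared(x, x), 1)
  expect_equal(r_squared(x, rep(2, 4)), 0)
  expect_error(r_squared(x, x[1:3]), "mismatch")
  set.seed(66)
  for (i in 1:10) {
    o <- rnorm(30); p <- rnorm(30)
    expect_equal(r_squared(o, p),
                 (cov(o, p) / (sd(o) * sd(p)))^2, tolerance = 1e-12)
    expect_equal(r_squared(o, p, method = "ss"),
                 1 - sum((o - p)^2) / sum((o - mean(o))^2))
  }
})

test_that("cross-validation: noiseless data give R2 = 1, folds are near-equal and seeded", {
  set.seed(67)
  n <- 140
  X <- data.frame(x = runif(n))
  y <- 0.9 - 0.3 * X$x
  cv <- cross_validate(y, X, "x", k = 7, repeats = 3, seed = 5)
  expect_equal(cv$mean_r2, 1)
  # n = 140, k = 7 -> every fold has exactly 20 observations; check via a
  # reconstruction of the same seeded partition
  set.seed(5)
  fold <- sample(rep_len(1:7, n))
  expect_true(all(table(fold) == 20))
  cv2 <- cross_validate(y, X, "x", k = 7, repeats = 3, seed = 5)
  expect_identical(cv$r2, cv2$r2)
  cv3 <- cross_validate(y, X, "x", k = 7, repeats = 3, seed = 6)
  expect_false(identical(cv$r2, cv3$r2))
  expect_equal(cv$sd_r2, sd(as.vector(cv$r2)))
})

test_that("held-out R2 approaches the analytic signal fraction at large n", {
  set.seed(68)
  n <- 1000
  x <- runif(n)
  signal <- 0.5 * x
  sigma <- sd(signal) * sqrt((1 - 0.5) / 0.5)   # analytic R2 = 0.5
  y <- 0.2 + signal + rnorm(n, sd = sigma)
  cv <- cross_validate(y, data.frame(x = x), "x", k = 7, repeats = 5,
                       seed = 9)
  expect_gt(cv$mean_r2, 0.45)
  expect_lt(cv$mean_r2, 0.55)
})

test_that("surface prediction equals a per-pixel dot-product oracle and clamps", {
  g <- grid_spec(0, 0, 500, 12, 10)
  set.seed(69)
  s1 <- impact_surface(matrix(runif(120), 10, 12), g, "roads")
  s2 <- impact_surface(matrix(runif(120, 0, 2000), 10, 12), g, "elevation")
  surfaces <- list(roads = s1, elevation = s2)
  # fit on sampled data
  sites <- data.frame(x = runif(80, 0, 6000), y = runif(80, 0, 5000))
  raw <- data.frame(roads = sample_surface(s1, sites$x, sites$y),
                    elevation = sample_surface(s2, sites$x, sites$y))
  sc <- scale_predictors(raw)
  yy <- 0.9 - 0.5 * sc$scaled$roads - 0.3 * sc$scaled$elevation +
    rnorm(80, sd = 0.02)
  fit <- fit_ols(yy, sc$scaled)
  pred <- predict_surface(fit, surfaces, sc$record)
  # oracle: scale each pixel by the record, dot with coefficients, clamp
  for (idx in sample(120, 20)) {
    v <- c(roads = as.vector(s1$values)[idx],
           elevation = as.vector(s2$values)[idx])
    vs <- (v - c(sc$record$min[1], sc$record$min[2])) /
      c(sc$record$max[1] - sc$record$min[1],
        sc$record$max[2] - sc$record$min[2])
    want <- min(1, max(0, sum(c(1, vs) * fit$coefficients)))
    expect_equal(as.vector(pred$values)[idx], want, tolerance = 1e-12)
  }
  # intercept-only fit projects a uniform surface
  f0 <- fit_ols(rep(0.7, 10) + rnorm(10, sd = 1e-9),
                data.frame()[1:10, , drop = FALSE])
  p0 <- predict_surface(f0, surfaces["roads"], sc$record)
  expect_equal(as.vector(p0$values), rep(f0$coefficients[[1]], 120))
  expect_error(predict_surface(fit, surfaces["roads"], sc$record),
               "no surface")
})
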