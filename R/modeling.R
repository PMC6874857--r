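# All-subsets Gaussian linear modeling under AICc with collinearity
# screening, repeated k-fold cross-validated R2, and projection of the
# selected model onto surfaces.

#' Min-max scale predictor columns to \[0, 1\]
#'
#' Every predictor (threat values and environmental variables alike) enters
#' the models on a common 0-1 scale. The per-column min/max are recorded so
#' the identical transform can be applied to new data (e.g. the full grid at
#' prediction time).
#'
#' @param table Data frame of numeric predictor columns.
#' @return A list with `scaled` (data frame) and `record` (data frame
#'   `column`, `min`, `max`). Constant columns scale to 0 with a warning.
#' @export
scale_predictors <- function(table) {
  stopifnot(is.data.frame(table))
  rec <- data.frame(column = names(table),
                    min = vapply(table, min, 0), max = vapply(table, max, 0),
                    stringsAsFactors = FALSE, row.names = NULL)
  scaled <- table
  for (j in seq_along(table)) {
    rng <- c(rec$min[j], rec$max[j])
    if (rng[2] == rng[1]) {
      warning(sprintf("constant predictor '%s' scaled to 0", names(table)[j]),
              call. = FALSE)
      scaled[[j]] <- rep(0, nrow(table))
    } else {
      scaled[[j]] <- (table[[j]] - rng[1]) / (rng[2] - rng[1])
    }
  }
  list(scaled = scaled, record = rec)
}

#' @rdname scale_predictors
#' @param record A scaling record from a previous `scale_predictors()` call.
#' @param new_table New data with the recorded columns.
#' @export
apply_scaling <- function(record, new_table) {
  out <- new_table[record$column]
  for (j in seq_len(nrow(record))) {
    rng <- c(record$min[j], record$max[j])
    out[[j]] <- if (rng[2] == rng[1]) rep(0, nrow(out)) else
      (out[[j]] - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' Ordinary least squares with Gaussian likelihood
#'
#' Fits `y ~ 1 + X` by QR least squares (the Gaussian-family GLM estimator)
#' and evaluates the Gaussian log-likelihood at the maximum-likelihood
#' variance `RSS/n`.
#'
#' @param y Response vector.
#' @param x Data frame or matrix of predictors (may have zero columns for
#'   the intercept-only model).
#' @return An object of class `ols_fit`: coefficients (`intercept` first),
#'   `sigma2` (MLE), `loglik`, `r2` (in-sample), `n`, `k` (number of
#'   likelihood parameters: coefficients + variance), fitted values and
#'   `aicc`.
#' @export
fit_ols <- function(y, x) {
  x <- as.data.frame(x)
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, as.matrix(x))
  p <- ncol(X)
  if (n <= p) stop("need n > number of coefficients", call. = FALSE)
  if (qr(X)$rank < p) {
    stop("rank-deficient design; collinear columns among: ",
         paste(colnames(X)[-1], collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  rss <- sum(res^2)
  sigma2 <- rss / n
  ll <- if (sigma2 == 0) Inf else
    -n / 2 * (log(2 * pi) + log(sigma2) + 1)
  tss <- sum((y - mean(y))^2)
  k <- p + 1L  # + variance parameter
  # classical coefficient SEs and t-test p-values (unbiased variance)
  XtXinv <- chol2inv(qr.R(qr(X)))
  se <- sqrt(diag(XtXinv) * rss / (n - p))
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  structure(list(terms = colnames(X)[-1], coefficients = fit$coefficients,
                 se = se, p_values = pval,
                 sigma2 = sigma2, loglik = ll,
                 r2 = if (tss > 0) 1 - rss / tss else 0,
                 n = n, k = k, fitted = fit$fitted.values,
                 aicc = aicc(ll, n, k)),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("ols_fit: %d term(s), n = %d, AICc = %.3f, R2 = %.3f\n",
              length(x$terms), x$n, x$aicc, x$r2))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`, where `k` counts the
#' intercept, slopes and the Gaussian variance parameter. Candidates with
#' `n <= k + 1` are inadmissible (`Inf`).
#'
#' @param loglik Maximized log-likelihood.
#' @param n Number of observations.
#' @param k Number of estimated parameters (including the variance).
#' @return The AICc value (`Inf` when the correction term is undefined).
#' @export
aicc <- function(loglik, n, k) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Enumerate admissible predictor subsets
#'
#' All subsets of size 0..`max_terms` that contain no pair of predictors
#' with absolute Pearson correlation above `collinearity_r`. Ordering is
#' deterministic: by size, then lexicographically in the order of
#' `predictors`.
#'
#' @param predictors Character vector of predictor names.
#' @param correlation Correlation matrix of the predictors (dimnames must
#'   cover `predictors`).
#' @param max_terms Largest subset size (7 for the local-scale scenarios,
#'   2 for the microbasin scenarios).
#' @param collinearity_r Exclusion threshold on |r| (default 0.7).
#' @return A list of character vectors (the empty subset first).
#' @export
enumerate_candidates <- function(predictors, correlation, max_terms = 7,
                                 collinearity_r = 0.7) {
  stopifnot(max_terms >= 0, collinearity_r > 0, collinearity_r <= 1)
  p <- length(predictors)
  bad_pair <- matrix(FALSE, p, p)
  if (p > 1) {
    cm <- correlation[predictors, predictors, drop = FALSE]
    bad_pair <- abs(cm) > collinearity_r
    diag(bad_pair) <- FALSE
  }
  out <- list(character(0))
  for (size in seq_len(min(max_terms, p))) {
    combos <- utils::combn(seq_len(p), size, simplify = FALSE)
    for (idx in combos) {
      if (size > 1 && any(bad_pair[idx, idx])) next
      out[[length(out) + 1L]] <- predictors[idx]
    }
  }
  out
}

#' Best-subset selection by AICc
#'
#' Fits every admissible candidate subset and selects the one with minimal
#' AICc; ties break toward fewer terms, then lexicographic order. The full
#' candidate table (every subset with its AICc, delta and in-sample R2) is
#' retained for sub-optimal-model reporting.
#'
#' @param y Response vector.
#' @param predictors Data frame of predictor columns (already scaled).
#' @param max_terms,collinearity_r See [enumerate_candidates()].
#' @return A list of class `model_selection`: `best` (an `ols_fit`),
#'   `best_terms`, and `table` (data frame `terms`, `n_terms`, `aicc`,
#'   `delta_aicc`, `r2`, sorted by AICc).
#' @export
select_best <- function(y, predictors, max_terms = 7, collinearity_r = 0.7) {
  predictors <- as.data.frame(predictors)
  constant <- vapply(predictors, function(v) stats::var(v) == 0, TRUE)
  if (any(constant)) {
    warning("dropping constant predictor(s): ",
            paste(names(predictors)[constant], collapse = ", "),
            call. = FALSE)
    predictors <- predictors[!constant]
  }
  if (!ncol(predictors))
    stop("no non-constant predictors to select from", call. = FALSE)
  cm <- if (ncol(predictors) > 1) stats::cor(predictors) else
    matrix(1, 1, 1, dimnames = list(names(predictors), names(predictors)))
  cands <- enumerate_candidates(names(predictors), cm, max_terms,
                                collinearity_r)
  nt <- lengths(cands)
  aiccs <- numeric(length(cands)); r2s <- numeric(length(cands))
  fits <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    fits[[i]] <- fit_ols(y, predictors[cands[[i]]])
    aiccs[i] <- fits[[i]]$aicc
    r2s[i] <- fits[[i]]$r2
  }
  if (all(!is.finite(aiccs)))
    stop("no admissible candidate (n too small for every subset)",
         call. = FALSE)
  # candidates arrive sorted by size then lexicographic, so which.min's
  # first-match rule is exactly the documented tie-break
  best_i <- which.min(aiccs)
  tab <- data.frame(
    terms = vapply(cands, function(s)
      if (length(s)) paste(s, collapse = "+") else "(intercept)", ""),
    n_terms = nt, aicc = aiccs, delta_aicc = aiccs - min(aiccs), r2 = r2s,
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$aicc, tab$n_terms, tab$terms), ]
  rownames(tab) <- NULL
  structure(list(best = fits[[best_i]], best_terms = cands[[best_i]],
                 table = tab),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("model_selection: %d candidates, best = {%s}\n",
              nrow(x$table),
              if (length(x$best_terms)) paste(x$best_terms, collapse = ", ")
              else "intercept"))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' Coefficient of determination between observed and predicted
#'
#' The squared Pearson correlation (the convention of standard
#' cross-validation tooling); defined as 0 when either vector is constant.
#' `method = "ss"` gives the 1 - SSE/SST variant instead (can be negative
#' out of sample).
#'
#' @param observed,predicted Equal-length numeric vectors (n >= 2).
#' @param method `"cor"` (default) or `"ss"`.
#' @return A single number.
#' @export
r_squared <- function(observed, predicted, method = c("cor", "ss")) {
  method <- match.arg(method)
  if (length(observed) != length(predicted))
    stop("length mismatch", call. = FALSE)
  if (length(observed) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (method == "ss") {
    tss <- sum((observed - mean(observed))^2)
    if (tss == 0) return(0)
    return(1 - sum((observed - predicted)^2) / tss)
  }
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) return(0)
  stats::cor(observed, predicted)^2
}

#' Repeated k-fold cross-validation of a fixed predictor subset
#'
#' For each repeat, the data are randomly split into `k` near-equal folds
#' (sizes differ by at most 1); each fold in turn is held out, the subset is
#' refit on the remaining folds, and the held-out R2 is recorded. The
#' summary is the mean and SD over all `k * repeats` values.
#'
#' @param y Response vector.
#' @param predictors Data frame of predictor columns.
#' @param terms Character vector naming the subset to refit (e.g.
#'   `select_best(...)$best_terms`).
#' @param k Number of folds (default 7).
#' @param repeats Number of random re-partitions (default 20).
#' @param seed Integer seed controlling the fold assignments.
#' @param method Held-out R2 convention, see [r_squared()].
#' @return A list of class `cv_result`: `mean_r2`, `sd_r2`, `r2` (matrix
#'   repeats x k), `k`, `repeats`, `seed`, `terms`.
#' @export
cross_validate <- function(y, predictors, terms, k = 7, repeats = 20,
                           seed = 1, method = c("cor", "ss")) {
  method <- match.arg(method)
  predictors <- as.data.frame(predictors)
  n <- length(y)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < 2 * k) stop("need n >= 2k for meaningful folds", call. = FALSE)
  set.seed(seed)
  r2 <- matrix(NA_real_, repeats, k)
  for (r in seq_len(repeats)) {
    fold <- sample(rep_len(seq_len(k), n))
    for (f in seq_len(k)) {
      test <- fold == f
      fit <- fit_ols(y[!test], predictors[!test, terms, drop = FALSE])
      pred <- predict_ols(fit, predictors[test, , drop = FALSE])
      r2[r, f] <- r_squared(y[test], pred, method = method)
    }
  }
  structure(list(mean_r2 = mean(r2), sd_r2 = stats::sd(as.vector(r2)),
                 r2 = r2, k = k, repeats = repeats, seed = seed,
                 terms = terms),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold x %d repeats, mean R2 = %.3f (SD %.3f)\n",
              x$k, x$repeats, x$mean_r2, x$sd_r2))
  invisible(x)
}

#' Predict from an OLS fit on new data
#'
#' @param fit An `ols_fit`.
#' @param newdata Data frame containing the fit's terms.
#' @return Numeric vector of linear predictions (unclamped).
#' @export
predict_ols <- function(fit, newdata) {
  stopifnot(inherits(fit, "ols_fit"))
  X <- cbind(1, as.matrix(as.data.frame(newdata)[fit$terms]))
  as.numeric(X %*% fit$coefficients)
}

#' Project the selected model onto the full grid
#'
#' Applies the stored predictor scaling to each pixel's surface values,
#' evaluates the linear model, and clamps predictions into \[0, 1\] (the EII
#' range), reporting how many pixels were clamped.
#'
#' @param fit An `ols_fit`.
#' @param surfaces Named list of `impact_surface`s covering every term of
#'   the fit (unscaled values, as sampled).
#' @param record Scaling record from [scale_predictors()].
#' @return An `impact_surface` of predicted EII, with
#'   `provenance$n_clamped`.
#' @export
predict_surface <- function(fit, surfaces, record) {
  stopifnot(inherits(fit, "ols_fit"))
  missing <- setdiff(fit$terms, names(surfaces))
  if (length(missing))
    stop("no surface for predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  g <- surfaces[[1]]$grid
  npix <- g$nrow * g$ncol
  raw <- as.data.frame(lapply(surfaces, function(s) as.vector(s$values)))
  names(raw) <- names(surfaces)
  scaled <- apply_scaling(record[record$column %in% names(raw), ], raw)
  pred <- predict_ols(fit, scaled)
  clamped <- sum(pred < 0 | pred > 1)
  pred <- pmin(1, pmax(0, pred))
  impact_surface(matrix(pred, g$nrow, g$ncol), g, name = "predicted_eii",
                 provenance = list(n_clamped = clamped, npix = npix,
                                   terms = fit$terms))
}
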