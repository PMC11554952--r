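#' Regression error metrics
#'
#' Computes the five-metric suite used throughout the package from observed
#' and predicted values: mean squared error, its square root, mean absolute
#' error, the coefficient of determination \eqn{R^2 = 1 - SSE/SST}, and
#' explained variance \eqn{EV = 1 - Var(y - \hat y)/Var(y)} (EV equals
#' \eqn{R^2} exactly when the residuals have zero mean).
#'
#' @param y Observed values.
#' @param y_hat Predicted values, same length.
#' @return A one-row tibble with columns `mse`, `rmse`, `mae`, `r2`, `ev`.
#' @examples
#' regression_metrics(c(0, 1), c(0.5, 0.5))
#' @export
regression_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat)) abort("`y` and `y_hat` must match in length.")
  res <- y - y_hat
  mse <- mean(res^2)
  sst <- sum((y - mean(y))^2)
  tibble(
    mse  = mse,
    rmse = sqrt(mse),
    mae  = mean(abs(res)),
    r2   = 1 - sum(res^2) / sst,
    ev   = 1 - var_pop(res) / var_pop(y)
  )
}

var_pop <- function(x) mean((x - mean(x))^2)

#' Create a subset-evaluation cache
#'
#' The weight search revisits the same feature subsets many times under
#' different weight vectors; an evaluation cache keyed by the sorted subset
#' stores each cross-validation result so it is computed once. Pass the cache
#' to [evaluate_subset()] or let [optimize_weights()] manage one internally.
#'
#' @return An environment with a `hits` counter.
#' @export
new_eval_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$hits <- 0L
  e$store <- new.env(parent = emptyenv())
  e
}

#' Cross-validated metrics of a feature subset
#'
#' Fits a linear least-squares regression of the (min-max-scaled) target on
#' the (min-max-scaled) subset of features under seeded k-fold
#' cross-validation, pools the out-of-fold predictions, and returns the
#' five-metric suite of [regression_metrics()]. Scaling is applied globally
#' before splitting (set `scale = "none"` to evaluate on the original units).
#' The fold assignment depends only on `seed`, `folds` and the number of
#' samples, so metrics for different subsets are comparable.
#'
#' @param data,target Data frame and target column name.
#' @param features Character vector of feature columns to use.
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed controlling the fold assignment.
#' @param scale `"minmax"` (default) or `"none"`.
#' @param cache Optional cache from [new_eval_cache()].
#' @return A one-row tibble: `mse`, `rmse`, `mae`, `r2`, `ev`.
#' @examples
#' d <- sim_regression(n = 50, p = 3, relevant = 1, effects = 2,
#'                     noise_sd = 0, seed = 1)
#' evaluate_subset(d, "y", "x1")   # mse 0, r2 1: y is an exact function of x1
#' @export
evaluate_subset <- function(data, target, features, folds = 5L, seed = 0L,
                            scale = c("minmax", "none"), cache = NULL) {
  scale <- match.arg(scale)
  if (length(features) == 0L) abort("`features` must be nonempty.")
  fs <- as_fs_data(data, target)
  missing <- setdiff(features, fs$feature_names)
  if (length(missing) > 0L) {
    abort(sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")))
  }
  if (folds < 2L) abort("`folds` must be at least 2.")
  features <- sort(features)  # canonical order: metrics and cache agree
  key <- paste(features, collapse = "\x1f")
  if (!is.null(cache) && !is.null(cache$store[[key]])) {
    cache$hits <- cache$hits + 1L
    return(cache$store[[key]])
  }
  X <- fs$X[, features, drop = FALSE]
  y <- fs$y
  if (scale == "minmax") {
    X <- minmax_scale(X)
    y <- minmax(y)
  }
  n <- nrow(X)
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  y_hat <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    Xtr <- cbind(1, X[!test, , drop = FALSE])
    fit <- stats::lm.fit(Xtr, y[!test])
    b <- fit$coefficients
    b[is.na(b)] <- 0  # rank-deficient training block: drop aliased columns
    y_hat[test] <- cbind(1, X[test, , drop = FALSE]) %*% b
  }
  out <- regression_metrics(y, y_hat)
  if (!is.null(cache)) cache$store[[key]] <- out
  out
}
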