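#' Per-method feature-importance scores
#'
#' Each scorer takes a data frame of samples by variables plus the name of the
#' target column and returns one importance score per feature as a tibble with
#' columns `feature` and `score`. All scores are nonnegative magnitudes:
#' signed statistics (Pearson r, lasso coefficients) are stored as absolute
#' values so that strongly anticorrelated features rank as important, and
#' negative permutation importances are clipped to zero.
#'
#' * `score_pearson()`: |Pearson correlation| between each feature and the
#'   target; requires nonconstant columns.
#' * `score_distance()`: sample distance correlation ([distance_cor()]), which
#'   also captures nonlinear dependence.
#' * `score_lasso()`: absolute lasso coefficients at the cross-validated
#'   penalty (`lambda.min`), features standardized internally.
#' * `score_rf()`: random-forest permutation importance (mean decrease in
#'   accuracy): increase in mean squared error when a feature's values are
#'   permuted, averaged over `n_perm` permutations of predictions from the
#'   fitted forest; negatives clipped to 0.
#' * `score_stability()`: stability selection — the fraction of `n_subsample`
#'   half-sized subsamples in which the feature enters the lasso support at a
#'   per-subsample cross-validated penalty; a selection frequency in \[0, 1\].
#'
#' @param data A data frame with numeric columns, no missing values.
#' @param target Name of the target column in `data`.
#' @param seed Integer seed; every stochastic scorer is bitwise reproducible
#'   under a fixed seed. The caller's RNG state is left untouched.
#' @param n_trees,n_perm Random-forest size and number of permutation repeats.
#' @param n_subsample Number of half-sized subsamples for stability selection.
#' @return A tibble with columns `feature` (in input column order) and `score`.
#' @seealso [score_features()] to stack several methods into one table.
#' @examples
#' d <- sim_regression(n = 80, p = 4, relevant = 1, effects = 3, seed = 1)
#' score_pearson(d, "y")
#' @name importance-scores
NULL

#' @rdname importance-scores
#' @export
score_pearson <- function(data, target) {
  fs <- as_fs_data(data, target)
  check_nonconstant(cbind(fs$X, setNames(data.frame(fs$y), fs$target_name)))
  score_tbl(fs$feature_names, abs(as.vector(cor(fs$X, fs$y))))
}

#' @rdname importance-scores
#' @export
score_distance <- function(data, target) {
  fs <- as_fs_data(data, target)
  check_nonconstant(cbind(fs$X, setNames(data.frame(fs$y), fs$target_name)))
  s <- vapply(seq_along(fs$feature_names),
              function(j) distance_cor(fs$X[, j], fs$y), numeric(1))
  score_tbl(fs$feature_names, s)
}

#' @rdname importance-scores
#' @export
score_lasso <- function(data, target, seed = 0L) {
  fs <- as_fs_data(data, target)
  if (length(fs$feature_names) < 2L) {
    # glmnet needs >= 2 columns; pad with a zero column that can never enter
    X <- cbind(fs$X, `.pad` = 0)
  } else {
    X <- fs$X
  }
  beta <- withr::with_seed(seed, {
    foldid <- sample(rep_len(1:10, nrow(X)))
    cvfit <- glmnet::cv.glmnet(X, fs$y, alpha = 1, foldid = foldid,
                               standardize = TRUE)
    as.vector(coef(cvfit, s = "lambda.min"))[-1]  # drop intercept
  })
  score_tbl(fs$feature_names, abs(beta[seq_along(fs$feature_names)]))
}

#' @rdname importance-scores
#' @export
score_rf <- function(data, target, seed = 0L, n_trees = 100L, n_perm = 10L) {
  fs <- as_fs_data(data, target)
  df <- as.data.frame(fs$X)
  df[[fs$target_name]] <- fs$y
  fit <- ranger::ranger(
    dependent.variable.name = fs$target_name, data = df,
    num.trees = n_trees, seed = seed, num.threads = 1L
  )
  base_mse <- mean((predict(fit, df, num.threads = 1L)$predictions - fs$y)^2)
  imp <- withr::with_seed(seed, {
    vapply(fs$feature_names, function(f) {
      inc <- vapply(seq_len(n_perm), function(r) {
        perm <- df
        perm[[f]] <- sample(perm[[f]])
        mean((predict(fit, perm, num.threads = 1L)$predictions - fs$y)^2) -
          base_mse
      }, numeric(1))
      mean(inc)
    }, numeric(1))
  })
  score_tbl(fs$feature_names, pmax(imp, 0))
}

#' @rdname importance-scores
#' @export
score_stability <- function(data, target, seed = 0L, n_subsample = 100L) {
  fs <- as_fs_data(data, target, min_n = 10L)
  p <- length(fs$feature_names)
  half <- floor(nrow(fs$X) / 2)
  hits <- withr::with_seed(seed, {
    acc <- numeric(p)
    for (b in seq_len(n_subsample)) {
      idx <- sample(nrow(fs$X), half)
      Xb <- fs$X[idx, , drop = FALSE]
      if (p < 2L) Xb <- cbind(Xb, `.pad` = 0)
      # skip degenerate subsamples where a column went constant
      if (any(apply(Xb, 2L, stats::sd)[seq_len(p)] == 0)) next
      foldid <- sample(rep_len(1:5, half))
      cvfit <- glmnet::cv.glmnet(Xb, fs$y[idx], alpha = 1, foldid = foldid,
                                 standardize = TRUE)
      beta <- as.vector(coef(cvfit, s = "lambda.min"))[-1]
      acc <- acc + (abs(beta[seq_len(p)]) > 0)
    }
    acc
  })
  score_tbl(fs$feature_names, hits / n_subsample)
}

score_tbl <- function(features, scores) {
  stopifnot(all(is.finite(scores)), all(scores >= 0))
  tibble(feature = features, score = unname(scores))
}

# Registry mapping method names to scorer closures; seeded scorers receive
# a distinct sub-seed so methods stay independent under one top-level seed.
fs_methods <- function() {
  list(
    pearson   = function(data, target, seed) score_pearson(data, target),
    distance  = function(data, target, seed) score_distance(data, target),
    lasso     = function(data, target, seed) score_lasso(data, target, seed = seed),
    rf        = function(data, target, seed) score_rf(data, target, seed = seed),
    stability = function(data, target, seed) score_stability(data, target, seed = seed)
  )
}

#' Stack per-method importance scores into one table
#'
#' Runs the requested importance methods and returns their scores in long
#' format — one row per (method, feature) pair — ready for
#' [normalize_scores()] and [compute_wts()]. Stochastic methods receive
#' method-specific sub-seeds derived from `seed`, so the whole table is
#' reproducible from a single integer.
#'
#' @inheritParams importance-scores
#' @param methods Character vector naming the methods to run, a subset of
#'   `c("pearson", "distance", "lasso", "rf", "stability")`; row order in the
#'   result follows this order.
#' @return A tibble of class `fs_importance` with columns `method`, `feature`,
#'   `score`; all scores are finite and nonnegative.
#' @examples
#' d <- sim_regression(n = 60, p = 4, relevant = 1, effects = 3, seed = 1)
#' score_features(d, "y", methods = c("pearson", "distance"))
#' @export
score_features <- function(data, target,
                           methods = c("pearson", "distance", "lasso",
                                       "rf", "stability"),
                           seed = 0L) {
  registry <- fs_methods()
  unknown <- setdiff(methods, names(registry))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown method(s): %s (available: %s)",
                  paste(unknown, collapse = ", "),
                  paste(names(registry), collapse = ", ")))
  }
  if (length(methods) == 0L) abort("`methods` must be nonempty.")
  rows <- purrr::imap(setNames(methods, methods), function(m, nm) {
    sub_seed <- (seed * 131L + match(m, names(registry))) %% .Machine$integer.max
    registry[[m]](data, target, seed = sub_seed)
  })
  out <- dplyr::bind_rows(rows, .id = "method")
  class(out) <- c("fs_importance", class(out))
  out
}

#' @export
autoplot.fs_importance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$feature, y = .data$method,
                                       fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
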