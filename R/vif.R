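#' Spearman rank-correlation matrix
#'
#' Pairwise Spearman correlations between the requested features, the usual
#' first screen for monotone redundancy before variance-inflation analysis.
#'
#' @param data Data frame of numeric columns.
#' @param features Character vector of at least two feature columns; default
#'   all columns.
#' @return A symmetric numeric matrix with unit diagonal.
#' @examples
#' d <- sim_regression(n = 50, p = 3, relevant = 1, effects = 1, seed = 1)
#' spearman_matrix(d, c("x1", "x2", "x3"))
#' @export
spearman_matrix <- function(data, features = NULL) {
  if (is.null(features)) features <- names(data)
  X <- feature_matrix(data, features, min_k = 2L)
  check_nonconstant(X)
  cor(X, method = "spearman")
}

#' Variance inflation factors
#'
#' Computes \eqn{VIF_j = 1 / (1 - R^2_j)} for each feature, where
#' \eqn{R^2_j} comes from the ordinary least-squares regression of feature j
#' on the remaining features plus an intercept. VIF is invariant to affine
#' rescaling of the columns, so it is computed on the data as given. A
#' feature that is perfectly explained by the others (\eqn{R^2_j = 1} within
#' 1e-12) gets `Inf` rather than an error.
#'
#' @inheritParams spearman_matrix
#' @return A tibble with columns `feature` and `vif` (each >= 1).
#' @examples
#' d <- sim_regression(n = 100, p = 4, relevant = 1, effects = 1, seed = 1,
#'                     cor_pairs = data.frame(i = 1, j = 2, rho = 0.95))
#' compute_vif(d, c("x1", "x2", "x3", "x4"))
#' @export
compute_vif <- function(data, features = NULL) {
  if (is.null(features)) features <- setdiff(names(data), "y")
  X <- feature_matrix(data, features, min_k = 2L)
  if (nrow(X) <= ncol(X)) {
    abort("need more samples than features to compute VIFs.")
  }
  vifs <- vapply(seq_along(features), function(j) {
    xj <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, xj)
    r2 <- 1 - sum(fit$residuals^2) / sum((xj - mean(xj))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(feature = features, vif = vifs)
}

#' Iterative VIF-based multicollinearity pruning
#'
#' Repeatedly computes VIFs for the current feature set and removes the
#' feature with the largest VIF while any VIF exceeds `threshold` (the
#' conventional cutoff is 10), recomputing after every removal since dropping
#' one member of a collinear group deflates the others. Ties in the maximum
#' VIF are broken by original column order, so the procedure is
#' deterministic. Stops when all VIFs are at or below the threshold or a
#' single feature remains.
#'
#' @inheritParams spearman_matrix
#' @param threshold VIF threshold (> 1); features above it are candidates for
#'   removal.
#' @return An object of class `vif_report`: list with `kept` (surviving
#'   features, original order), `removed` (tibble of removal steps, columns
#'   `feature`, `vif`), `vif` (final per-feature tibble), and `threshold`.
#' @examples
#' d <- sim_regression(n = 100, p = 4, relevant = 1, effects = 1, seed = 1,
#'                     cor_pairs = data.frame(i = 1, j = 2, rho = 0.99))
#' prune_by_vif(d, c("x1", "x2", "x3", "x4"), threshold = 10)
#' @export
prune_by_vif <- function(data, features = NULL, threshold = 10) {
  if (threshold <= 1) abort("`threshold` must exceed 1.")
  if (is.null(features)) features <- setdiff(names(data), "y")
  current <- features
  removed <- tibble(feature = character(), vif = numeric())
  repeat {
    if (length(current) < 2L) break
    vt <- compute_vif(data, current)
    if (max(vt$vif) <= threshold) break
    worst <- which.max(vt$vif)  # which.max takes the first tie: column order
    removed <- dplyr::bind_rows(
      removed, tibble(feature = vt$feature[worst], vif = vt$vif[worst]))
    current <- current[-worst]
  }
  final <- if (length(current) >= 2L) compute_vif(data, current)
           else tibble(feature = current, vif = NA_real_)
  structure(list(kept = current, removed = removed, vif = final,
                 threshold = threshold), class = "vif_report")
}

feature_matrix <- function(data, features, min_k = 1L) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  missing <- setdiff(features, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("unknown feature(s): %s", paste(missing, collapse = ", ")))
  }
  if (length(features) < min_k) {
    abort(sprintf("need at least %d features.", min_k))
  }
  X <- as.matrix(data[features])
  if (!is.numeric(X) || anyNA(X)) abort("features must be numeric, no NAs.")
  X
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("VIF pruning at threshold %.3g\n", x$threshold))
  if (nrow(x$removed) > 0L) {
    cat("  removed:",
        paste(sprintf("%s (VIF %.2f)", x$removed$feature, x$removed$vif),
              collapse = ", "), "\n")
  } else {
    cat("  nothing removed\n")
  }
  cat("  kept:", paste(x$kept, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a VIF pruning report
#'
#' `tidy()` returns one row per feature with its final VIF (NA if removed)
#' and a `removed` flag; `glance()` summarizes the pruning in one row.
#'
#' @param x A `vif_report` from [prune_by_vif()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.vif_report <- function(x, ...) {
  dplyr::bind_rows(
    x$vif |> dplyr::mutate(removed = FALSE),
    x$removed |> dplyr::mutate(vif = NA_real_, removed = TRUE)
  )
}

#' @rdname tidy.vif_report
#' @export
glance.vif_report <- function(x, ...) {
  tibble(n_kept = length(x$kept), n_removed = nrow(x$removed),
         max_vif = if (all(is.na(x$vif$vif))) NA_real_ else max(x$vif$vif),
         threshold = x$threshold)
}

#' @export
autoplot.vif_report <- function(object, ...) {
  df <- object$vif[!is.na(object$vif$vif), ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$vif, y = stats::reorder(.data$feature, .data$vif))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "variance inflation factor", y = NULL) +
    ggplot2::theme_minimal()
}
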