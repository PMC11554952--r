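#' Min-max normalize an importance table
#'
#' Rescales every method's scores linearly to \[0, 1\] using that method's own
#' minimum and maximum, so methods with incommensurable raw scales (correlation
#' magnitudes, coefficients, selection frequencies) become comparable before
#' they are aggregated. A method whose scores are all equal carries no ranking
#' information; its row is mapped to all zeros (with a warning), which leaves a
#' uniform contribution to every feature and cannot change the ranking.
#'
#' @param scores A tibble with columns `method`, `feature`, `score` (as
#'   returned by [score_features()]), or any data frame with those columns.
#' @return A tibble of class `fs_importance_norm` with the same columns;
#'   within each method the scores span exactly \[0, 1\] unless constant.
#' @examples
#' tbl <- tibble::tibble(method = "m", feature = c("a", "b", "c"),
#'                       score = c(0, 5, 10))
#' normalize_scores(tbl)$score   # 0, 0.5, 1
#' @export
normalize_scores <- function(scores) {
  scores <- check_score_tbl(scores)
  if (!all(is.finite(scores$score))) abort("scores must be finite.")
  const <- scores |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(const = max(.data$score) == min(.data$score)) |>
    dplyr::filter(.data$const)
  if (nrow(const) > 0L) {
    warn(sprintf("method(s) with constant scores mapped to all zeros: %s",
                 paste(const$method, collapse = ", ")))
  }
  out <- scores |>
    dplyr::group_by(.data$method) |>
    dplyr::mutate(score = minmax(.data$score)) |>
    dplyr::ungroup()
  class(out) <- c("fs_importance_norm", setdiff(class(out), "fs_importance"))
  out
}

#' Weighted Total Score of each feature
#'
#' Aggregates normalized per-method importances into a single Weighted Total
#' Score per feature,
#' \deqn{WTS_j = \sum_i W_i \, e^{\tilde F_{ij}},}
#' where the method weights \eqn{W_i} are nonnegative and sum to one. The
#' exponential map magnifies differences near the top of each method's scale
#' and bounds every WTS in \[1, e\]: a feature scores exactly 1 only if every
#' positively-weighted method gave it the minimum normalized score, and
#' exactly e only if every such method gave it the maximum.
#'
#' @param normed A normalized importance table from [normalize_scores()].
#' @param weights Numeric vector of method weights, one per method (in the
#'   method order of `normed`, or named by method); must be nonnegative and
#'   sum to 1 within 1e-9.
#' @return A tibble of class `wts_ranking` with columns `feature`, `wts`,
#'   `rank`, sorted by descending WTS; ties keep the original feature-column
#'   order, so rankings are reproducible bit for bit.
#' @examples
#' tbl <- tibble::tibble(method = rep(c("a", "b"), each = 2),
#'                       feature = rep(c("x1", "x2"), 2),
#'                       score = c(0, 1, 0, 1))
#' compute_wts(normalize_scores(tbl), c(0.5, 0.5))
#' @export
compute_wts <- function(normed, weights) {
  normed <- check_score_tbl(normed)
  methods <- unique(normed$method)
  features <- unique(normed$feature)
  if (!is.null(names(weights)) && all(methods %in% names(weights))) {
    weights <- weights[methods]
  }
  if (length(weights) != length(methods)) {
    abort(sprintf("`weights` must have length %d (one per method).",
                  length(methods)))
  }
  if (any(weights < 0)) abort("weights must be nonnegative.")
  if (abs(sum(weights) - 1) > 1e-9) {
    abort(sprintf("weights must sum to 1 (got %.12f).", sum(weights)))
  }
  if (any(normed$score < 0 | normed$score > 1)) {
    abort("`normed` scores must lie in [0, 1]; run normalize_scores() first.")
  }
  Ft <- tidyr::pivot_wider(normed, id_cols = "feature",
                           names_from = "method", values_from = "score")
  M <- as.matrix(Ft[methods])
  wts <- as.vector(exp(M) %*% unname(weights))
  ord <- order(-wts, seq_along(wts))  # ties keep original column order
  tibble(feature = Ft$feature[ord], wts = wts[ord],
         rank = seq_along(wts)) |>
    structure(class = c("wts_ranking", class(tibble())))
}

#' Select the top-k features of a WTS ranking
#'
#' @param ranking A `wts_ranking` tibble from [compute_wts()].
#' @param k Number of features to keep, between 1 and the number ranked.
#' @return Character vector of the first `k` feature names in rank order.
#' @export
select_top_k <- function(ranking, k) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k)) {
    abort("`k` must be a single integer.")
  }
  p <- nrow(ranking)
  if (k < 1 || k > p) {
    abort(sprintf("`k` must be in [1, %d], got %s.", p, format(k)))
  }
  ranking$feature[seq_len(k)]
}

check_score_tbl <- function(scores) {
  if (!is.data.frame(scores) ||
      !all(c("method", "feature", "score") %in% names(scores))) {
    abort("expected a data frame with columns method, feature, score.")
  }
  as_tibble(scores)
}

#' @export
autoplot.wts_ranking <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$wts, y = stats::reorder(.data$feature, .data$wts))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = c(1, exp(1)), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Weighted Total Score", y = NULL) +
    ggplot2::theme_minimal()
}
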