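# Weight search over the delta-lattice of the probability simplex.
#
# The candidate weight vectors live on the lattice {w : w_i = m_i * delta,
# sum w_i = 1}; the greedy search moves one delta unit of weight between two
# methods at a time, so every move preserves the simplex constraint exactly
# (weights are represented internally as integer multiples of delta).

#' Neighboring weight vectors on the delta-lattice
#'
#' Returns every weight vector reachable from `w` by transferring one `delta`
#' unit of weight from one method to another while keeping all weights
#' nonnegative. Together with the equal-weight start these moves connect the
#' whole lattice, and each preserves the sum-to-one constraint by
#' construction.
#'
#' @param w Numeric weight vector on the lattice (nonnegative, sums to 1).
#' @param delta Lattice step size; `1/delta` must be an integer.
#' @return A list of numeric weight vectors.
#' @examples
#' enumerate_weight_moves(c(0.5, 0.5), 0.5)
#' @export
enumerate_weight_moves <- function(w, delta) {
  check_delta(delta)
  units <- weights_to_units(w, delta)
  n <- length(units)
  out <- list()
  for (from in seq_len(n)) {
    if (units[from] == 0L) next
    for (to in seq_len(n)) {
      if (to == from) next
      u <- units
      u[from] <- u[from] - 1L
      u[to] <- u[to] + 1L
      out[[length(out) + 1L]] <- u * delta
    }
  }
  out
}

#' All weight vectors on the delta-lattice
#'
#' Enumerates the full lattice (all compositions of `1/delta` into as many
#' nonnegative parts as there are methods). Used by the exhaustive search
#' mode, which serves as the brute-force oracle for the greedy search on
#' small lattices.
#'
#' @inheritParams enumerate_weight_moves
#' @param n_methods Number of methods.
#' @return A list of weight vectors covering the simplex lattice.
#' @export
enumerate_weight_lattice <- function(n_methods, delta) {
  check_delta(delta)
  m <- as.integer(round(1 / delta))
  compose <- function(total, parts) {
    if (parts == 1L) return(list(total))
    out <- list()
    for (first in 0:total) {
      for (rest in compose(total - first, parts - 1L)) {
        out[[length(out) + 1L]] <- c(first, rest)
      }
    }
    out
  }
  lapply(compose(m, n_methods), function(u) u * delta)
}

check_delta <- function(delta) {
  if (delta <= 0 || delta > 1) abort("`delta` must be in (0, 1].")
  m <- 1 / delta
  if (abs(m - round(m)) > 1e-9) abort("1/delta must be an integer.")
  invisible(TRUE)
}

weights_to_units <- function(w, delta) {
  units <- as.integer(round(w / delta))
  if (any(units < 0) || abs(sum(units) * delta - 1) > 1e-9 ||
      max(abs(units * delta - w)) > 1e-9) {
    abort("`w` must lie on the delta-lattice of the probability simplex.")
  }
  units
}

# Equal weights snapped to the lattice by largest-remainder rounding;
# exact when n_methods divides 1/delta.
equal_weight_start <- function(n_methods, delta) {
  m <- as.integer(round(1 / delta))
  base <- m %/% n_methods
  units <- rep(base, n_methods)
  left <- m - base * n_methods
  if (left > 0L) units[seq_len(left)] <- units[seq_len(left)] + 1L
  units * delta
}

# Objective order: MSE ascending, then R^2 descending, then smaller k, then
# lexicographically smallest weight vector. Returns TRUE if `a` is strictly
# better than `b`.
obj_better <- function(a, b) {
  if (a$mse != b$mse) return(a$mse < b$mse)
  if (a$r2 != b$r2) return(a$r2 > b$r2)
  if (!is.null(a$k) && !is.null(b$k) && a$k != b$k) return(a$k < b$k)
  if (!is.null(a$w) && !is.null(b$w)) {
    d <- a$w - b$w
    nz <- which(d != 0)
    if (length(nz) > 0L) return(d[nz[1]] < 0)
  }
  FALSE
}

#' Optimize method weights and feature count
#'
#' Searches the delta-lattice of method weights and the feature count `k`
#' for the combination whose top-k WTS feature subset minimizes
#' cross-validated MSE (ties broken by higher R-squared, then smaller k, then
#' the lexicographically smallest weight vector). For each `k` the greedy
#' search starts from equal weights and repeatedly accepts the best
#' single-delta weight transfer that improves the objective, stopping at a
#' local optimum or after `max_iter` iterations; `restarts = "vertices"` adds
#' one restart from each unit vector, and `search = "exhaustive"` scores the
#' entire lattice (feasible for small `1/delta` and few methods, and used as
#' the oracle in the package's own tests). Subset evaluations are memoized:
#' distinct weight vectors that select the same subset cost one fit.
#'
#' @param data,target Data frame and target column name.
#' @param importance Optional importance table from [score_features()]; when
#'   `NULL` it is computed with `methods` and `seed`.
#' @param methods Methods to score when `importance` is `NULL`.
#' @param delta Weight lattice step; `1/delta` must be an integer.
#' @param max_iter Maximum greedy iterations per start.
#' @param k_range Integer range of subset sizes to consider, default `1:p`.
#' @param folds,seed Cross-validation folds and seed for [evaluate_subset()]
#'   (the same seed also drives scoring when `importance` is `NULL`).
#' @param search `"greedy"` (default) or `"exhaustive"`.
#' @param restarts `"none"` or `"vertices"`.
#' @param scale Passed to [evaluate_subset()].
#' @return An object of class `wts_fit`: a list with elements `w_star` (named
#'   weights), `k_star`, `selected` (features in rank order), `metrics`
#'   (one-row tibble), `ranking` (the WTS ranking at the optimum), `baselines`
#'   (equal-weight and single-method comparison rows), `iterations_used`,
#'   `cache_hits`, `evaluations`, and the search settings.
#' @examples
#' d <- sim_regression(n = 80, p = 5, relevant = 1:2, effects = c(3, 2), seed = 1)
#' imp <- score_features(d, "y", methods = c("pearson", "distance"), seed = 1)
#' fit <- optimize_weights(d, "y", importance = imp, delta = 0.5)
#' glance(fit)
#' @export
optimize_weights <- function(data, target, importance = NULL,
                             methods = c("pearson", "distance", "lasso",
                                         "rf", "stability"),
                             delta = 0.1, max_iter = 1000L, k_range = NULL,
                             folds = 5L, seed = 0L,
                             search = c("greedy", "exhaustive"),
                             restarts = c("none", "vertices"),
                             scale = "minmax") {
  search <- match.arg(search)
  restarts <- match.arg(restarts)
  check_delta(delta)
  if (max_iter < 1L) abort("`max_iter` must be positive.")
  fs <- as_fs_data(data, target)
  if (is.null(importance)) {
    importance <- score_features(data, target, methods = methods, seed = seed)
  }
  importance <- check_score_tbl(importance)
  if (!setequal(unique(importance$feature), fs$feature_names)) {
    abort("`importance` and `data` must share the same feature names.")
  }
  method_names <- unique(importance$method)
  n_methods <- length(method_names)
  p <- length(fs$feature_names)
  if (is.null(k_range)) k_range <- seq_len(p)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L) || any(k_range > p)) {
    abort(sprintf("`k_range` must lie within [1, %d].", p))
  }

  normed <- suppressWarnings(normalize_scores(importance))
  cache <- new_eval_cache()
  evals <- 0L
  eval_w <- function(w, k) {
    ranking <- compute_wts(normed, w)
    subset <- select_top_k(ranking, k)
    evals <<- evals + 1L
    m <- evaluate_subset(data, target, subset, folds = folds, seed = seed,
                         scale = scale, cache = cache)
    list(mse = m$mse, r2 = m$r2, k = k, w = w, metrics = m,
         ranking = ranking, selected = subset)
  }

  iterations_used <- 0L
  climb <- function(w0, k) {
    cur <- eval_w(w0, k)
    for (it in seq_len(max_iter)) {
      iterations_used <<- iterations_used + 1L
      best_nb <- NULL
      for (w in enumerate_weight_moves(cur$w, delta)) {
        cand <- eval_w(w, k)
        if (is.null(best_nb) || obj_better(cand, best_nb)) best_nb <- cand
      }
      if (!is.null(best_nb) && obj_better(best_nb, cur)) cur <- best_nb
      else break
    }
    cur
  }

  best <- NULL
  for (k in k_range) {
    if (search == "exhaustive") {
      for (w in enumerate_weight_lattice(n_methods, delta)) {
        cand <- eval_w(w, k)
        if (is.null(best) || obj_better(cand, best)) best <- cand
      }
    } else {
      starts <- list(equal_weight_start(n_methods, delta))
      if (restarts == "vertices" && n_methods > 1L) {
        m_units <- as.integer(round(1 / delta))
        for (i in seq_len(n_methods)) {
          u <- rep(0L, n_methods)
          u[i] <- m_units
          starts[[length(starts) + 1L]] <- u * delta
        }
      }
      for (w0 in starts) {
        cand <- climb(w0, k)
        if (is.null(best) || obj_better(cand, best)) best <- cand
      }
    }
  }

  baselines <- optimizer_baselines(normed, method_names, k_range, eval_w,
                                   delta, n_methods)

  structure(list(
    w_star = setNames(best$w, method_names),
    k_star = best$k,
    selected = best$selected,
    metrics = best$metrics,
    ranking = best$ranking,
    baselines = baselines,
    iterations_used = iterations_used,
    cache_hits = cache$hits,
    evaluations = evals,
    delta = delta, folds = folds, seed = seed, search = search,
    k_range = k_range, method_names = method_names
  ), class = "wts_fit")
}

# Equal-weight and single-method baseline rows (best k for each), mirroring
# the usual comparison-table layout.
optimizer_baselines <- function(normed, method_names, k_range, eval_w,
                                delta, n_methods) {
  best_over_k <- function(w) {
    best <- NULL
    for (k in k_range) {
      cand <- eval_w(w, k)
      if (is.null(best) || obj_better(cand, best)) best <- cand
    }
    best
  }
  rows <- list()
  for (i in seq_along(method_names)) {
    w <- rep(0, n_methods)
    w[i] <- 1
    b <- best_over_k(w)
    rows[[length(rows) + 1L]] <-
      dplyr::bind_cols(tibble(method = method_names[i], k = b$k), b$metrics)
  }
  eq <- best_over_k(rep(1 / n_methods, n_methods))
  rows[[length(rows) + 1L]] <-
    dplyr::bind_cols(tibble(method = "equal_weight", k = eq$k), eq$metrics)
  dplyr::bind_rows(rows)
}

#' @export
print.wts_fit <- function(x, ...) {
  cat("Weighted Total Score selection\n")
  cat(sprintf("  k* = %d, selected: %s\n", x$k_star,
              paste(x$selected, collapse = ", ")))
  cat("  W* =", paste(sprintf("%s=%.3g", names(x$w_star), x$w_star),
                      collapse = ", "), "\n")
  m <- x$metrics
  cat(sprintf("  MSE %.4g  RMSE %.4g  MAE %.4g  R2 %.4g  EV %.4g\n",
              m$mse, m$rmse, m$mae, m$r2, m$ev))
  cat(sprintf("  %d evaluations (%d cache hits), %d greedy iterations\n",
              x$evaluations, x$cache_hits, x$iterations_used))
  invisible(x)
}

#' Tidy a WTS selection
#'
#' `tidy()` returns the WTS ranking at the optimum with a `selected` flag;
#' `glance()` returns a one-row summary (optimal weights are in `w_star` of
#' the fit object itself).
#'
#' @param x A `wts_fit` from [optimize_weights()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wts_fit <- function(x, ...) {
  x$ranking |>
    dplyr::mutate(selected = .data$rank <= x$k_star)
}

#' @rdname tidy.wts_fit
#' @export
glance.wts_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble(k_star = x$k_star,
           iterations_used = x$iterations_used,
           evaluations = x$evaluations,
           cache_hits = x$cache_hits),
    x$metrics
  )
}

#' @export
autoplot.wts_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$wts, y = stats::reorder(.data$feature, .data$wts),
    fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "Weighted Total Score", y = NULL, fill = "selected") +
    ggplot2::theme_minimal()
}
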