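# Causal stage: a LiNGAM-style ordering of the selected variables, OLS edge
# estimation with Wald pruning along that order, and normal-theory
# significance tests for the resulting recursive path model.

#' Estimate a causal order by iterative exogeneity search
#'
#' Implements a DirectLiNGAM-style ordering for linear models with
#' non-Gaussian noise: at each step the most exogenous remaining variable is
#' the one minimizing the total distance correlation between itself and the
#' residuals of every other remaining variable regressed on it (for a truly
#' exogenous variable those residuals are independent of it). That variable
#' is appended to the order, the remaining variables are replaced by their
#' residuals, and the step repeats. Identification requires non-Gaussian
#' noise; with Gaussian data both directions explain the covariance equally
#' well and the ordering is arbitrary.
#'
#' Distance correlation costs O(n^2) memory and time, so the independence
#' statistic is evaluated on a deterministic subsample of at most
#' `dcor_max_n` rows (seeded); coefficient estimation downstream always uses
#' all rows.
#'
#' @param data Data frame of numeric columns.
#' @param vars Variables to order (default: all columns). With two or more
#'   variables at least 30 samples are required.
#' @param seed Seed for the dcor row subsample (only relevant when
#'   `nrow(data) > dcor_max_n`).
#' @param dcor_max_n Row cap for the independence statistic.
#' @return Character vector: the variables ordered from most exogenous to
#'   most downstream.
#' @examples
#' sim <- sim_lingam(matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE), n = 500,
#'                   seed = 1)
#' lingam_order(sim$data)  # "x1" then "x2"
#' @export
lingam_order <- function(data, vars = NULL, seed = 0L, dcor_max_n = 2000L) {
  if (is.null(vars)) vars <- names(data)
  X <- feature_matrix(data, vars, min_k = 1L)
  if (length(vars) == 1L) return(vars)
  if (nrow(X) < 30L) abort("need at least 30 samples to estimate an order.")
  check_nonconstant(X, what = "variable")
  X <- scale(X)  # standardize; exogeneity statistic is scale-free
  n <- nrow(X)
  idx <- if (n > dcor_max_n) {
    withr::with_seed(seed, sample(n, dcor_max_n))
  } else {
    seq_len(n)
  }
  order_out <- character(0)
  remaining <- vars
  M <- X
  while (length(remaining) > 1L) {
    total_dep <- vapply(seq_along(remaining), function(j) {
      xj <- M[, j]
      vj <- mean(xj^2) - mean(xj)^2
      dep <- 0
      for (k in seq_along(remaining)) {
        if (k == j) next
        b <- (mean(M[, k] * xj) - mean(M[, k]) * mean(xj)) / vj
        r <- M[, k] - b * xj
        dep <- dep + distance_cor(xj[idx], r[idx])
      }
      dep
    }, numeric(1))
    j <- which.min(total_dep)  # first minimum: deterministic tie-break
    xj <- M[, j]
    vj <- mean(xj^2) - mean(xj)^2
    for (k in seq_along(remaining)) {
      if (k == j) next
      b <- (mean(M[, k] * xj) - mean(M[, k]) * mean(xj)) / vj
      M[, k] <- M[, k] - b * xj
    }
    order_out <- c(order_out, remaining[j])
    M <- M[, -j, drop = FALSE]
    remaining <- remaining[-j]
  }
  c(order_out, remaining)
}

#' Estimate a pruned causal graph along an order
#'
#' Given (or first estimating) a causal order, regresses each variable by
#' ordinary least squares on all its predecessors and keeps the edges whose
#' Wald test is significant at `alpha`; coefficients are reported on the
#' scale of the data as given. The result is acyclic by construction since
#' edges only point forward along the order.
#'
#' @inheritParams lingam_order
#' @param alpha Wald-test significance level for keeping an edge.
#' @param order Optional known causal order (character vector); estimated via
#'   [lingam_order()] when `NULL`.
#' @return An object of class `causal_graph`: list with `nodes`,
#'   `causal_order`, and `edges` (tibble `from`, `to`, `estimate`, `std_err`,
#'   `p_value`).
#' @examples
#' B <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)
#' sim <- sim_lingam(B, n = 500, seed = 1)
#' lingam_fit(sim$data)
#' @export
lingam_fit <- function(data, vars = NULL, alpha = 0.05, order = NULL,
                       seed = 0L, dcor_max_n = 2000L) {
  if (is.null(vars)) vars <- names(data)
  if (is.null(order)) {
    order <- lingam_order(data, vars, seed = seed, dcor_max_n = dcor_max_n)
  }
  if (!setequal(order, vars)) abort("`order` must be a permutation of `vars`.")
  X <- feature_matrix(data, order, min_k = 1L)
  edges <- list()
  n <- nrow(X)
  for (i in seq_along(order)[-1]) {
    preds <- order[seq_len(i - 1L)]
    Z <- cbind(`(Intercept)` = 1, X[, preds, drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      abort(sprintf("predecessors of '%s' are collinear; prune first.",
                    order[i]))
    }
    b <- qr.coef(qz, X[, i])
    res <- X[, i] - Z %*% b
    df_res <- n - ncol(Z)
    sigma2 <- sum(res^2) / df_res
    se <- sqrt(diag(chol2inv(qr.R(qz))) * sigma2)
    tval <- b / se
    pval <- 2 * stats::pt(-abs(tval), df_res)
    for (r in seq_along(preds)) {
      if (pval[r + 1L] < alpha) {
        edges[[length(edges) + 1L]] <- tibble(
          from = preds[r], to = order[i],
          estimate = unname(b[r + 1L]), std_err = unname(se[r + 1L]),
          p_value = unname(pval[r + 1L]))
      }
    }
  }
  edges <- if (length(edges) > 0L) dplyr::bind_rows(edges) else
    tibble(from = character(), to = character(), estimate = numeric(),
           std_err = numeric(), p_value = numeric())
  g <- structure(list(nodes = order, causal_order = order, edges = edges,
                      alpha = alpha), class = "causal_graph")
  stopifnot(graph_is_acyclic(g))
  g
}

# Internal: edges must point forward along causal_order.
graph_is_acyclic <- function(g) {
  pos <- match(g$edges$from, g$causal_order) < match(g$edges$to, g$causal_order)
  all(pos)
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("Causal graph over %d variables (order: %s)\n",
              length(x$nodes), paste(x$causal_order, collapse = " -> ")))
  if (nrow(x$edges) == 0L) cat("  no edges retained\n") else {
    for (i in seq_len(nrow(x$edges))) {
      e <- x$edges[i, ]
      cat(sprintf("  %s -> %s  (%.3f, p = %.2g)\n",
                  e$from, e$to, e$estimate, e$p_value))
    }
  }
  invisible(x)
}

#' @export
tidy.causal_graph <- function(x, ...) x$edges

#' Fit and test a recursive linear path model
#'
#' Fits the system of linear equations implied by a directed acyclic set of
#' paths by maximum likelihood on the covariance matrix of the (by default
#' min-max-scaled) variables, and reports each path with its estimate,
#' standard error, z value and two-sided normal p value. For a recursive
#' model with uncorrelated residuals the ML point estimates coincide with
#' equation-wise least squares; standard errors come from the expected Fisher
#' information of the covariance-structure likelihood evaluated at the
#' model-implied covariance, with variances and covariances of the exogenous
#' variables held at their sample values. z values are invariant to affine
#' rescaling of individual variables, so conclusions do not depend on the
#' scaling choice.
#'
#' @param data Data frame containing every variable named in the paths.
#' @param paths A `causal_graph` from [lingam_fit()], or a data frame with
#'   columns `from` and `to` (one row per directed path).
#' @param scale `"minmax"` (default), `"standardize"`, or `"none"` — applied
#'   per variable before fitting.
#' @return A tibble of class `path_model` with columns `from`, `to`,
#'   `estimate`, `std_err`, `z`, `p_value`, in the order the paths were
#'   given.
#' @examples
#' d <- load_diabetes()
#' paths <- data.frame(
#'   from = c("GLU", "LTG", "TC", "LTG", "ABP", "BMI"),
#'   to   = c("LTG", "TC", "LDL", "Target", "Target", "Target"))
#' fit_path_model(d, paths)
#' @export
fit_path_model <- function(data, paths, scale = c("minmax", "standardize",
                                                  "none")) {
  scale <- match.arg(scale)
  edges <- if (inherits(paths, "causal_graph")) paths$edges else
    as_tibble(paths)
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`paths` must have columns `from` and `to`.")
  }
  if (nrow(edges) == 0L) abort("`paths` must contain at least one path.")
  if (any(edges$from == edges$to)) {
    abort("a path's source must differ from its target.")
  }
  nodes <- topological_order(edges)
  X <- feature_matrix(data, nodes, min_k = 2L)
  check_nonconstant(X, what = "variable")
  X <- switch(scale,
              minmax = minmax_scale(X),
              standardize = scale(X),
              none = X)
  n <- nrow(X)
  S <- cov(X)
  p <- length(nodes)
  endo <- unique(edges$to)
  exog <- setdiff(nodes, endo)
  eni <- match(endo, nodes)
  exi <- match(exog, nodes)
  nb <- nrow(edges)

  # ML point estimates: equation-wise least squares computed from S.
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  Psi <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (length(exog) > 0L) Psi[exi, exi] <- S[exog, exog]
  for (v in endo) {
    pa <- edges$from[edges$to == v]
    b <- solve(S[pa, pa, drop = FALSE], S[pa, v])
    psi_v <- S[v, v] - sum(S[v, pa] * b)
    if (psi_v <= 1e-12 * S[v, v]) {
      abort(sprintf(
        "singular path model: '%s' has (numerically) zero residual variance.",
        v))
    }
    B[v, pa] <- b
    Psi[v, v] <- psi_v
  }
  Ainv <- solve(diag(p) - B)
  Sigma <- Ainv %*% Psi %*% t(Ainv)

  # Expected Fisher information over the free parameters: the nb path
  # coefficients and the residual variances of the endogenous variables.
  Delta <- vector("list", nb + length(endo))
  for (i in seq_len(nb)) {
    dB <- matrix(0, p, p)
    dB[match(edges$to[i], nodes), match(edges$from[i], nodes)] <- 1
    dAinv <- Ainv %*% dB %*% Ainv
    Delta[[i]] <- dAinv %*% Psi %*% t(Ainv) + Ainv %*% Psi %*% t(dAinv)
  }
  for (j in seq_along(endo)) {
    dP <- matrix(0, p, p)
    dP[eni[j], eni[j]] <- 1
    Delta[[nb + j]] <- Ainv %*% dP %*% t(Ainv)
  }
  Sinv <- solve(Sigma)
  m <- length(Delta)
  J <- matrix(0, m, m)
  SD <- lapply(Delta, function(D) Sinv %*% D)
  for (i in seq_len(m)) {
    for (j in i:m) {
      J[i, j] <- J[j, i] <- sum(SD[[i]] * t(SD[[j]]))
    }
  }
  acov <- solve((n / 2) * J)
  est <- vapply(seq_len(nb),
                function(i) B[match(edges$to[i], nodes),
                              match(edges$from[i], nodes)],
                numeric(1))
  se <- sqrt(diag(acov))[seq_len(nb)]
  z <- est / se
  out <- tibble(from = edges$from, to = edges$to, estimate = est,
                std_err = se, z = z, p_value = 2 * pnorm(-abs(z)))
  structure(out, class = c("path_model", class(out)),
            nodes = nodes, exogenous = exog, n = n, scale = scale)
}

#' @export
glance.path_model <- function(x, ...) {
  tibble(n = attr(x, "n"), n_paths = nrow(x),
         n_nodes = length(attr(x, "nodes")),
         n_significant = sum(x$p_value < 0.05))
}

# Internal: topological sort of the nodes appearing in an edge table;
# errors on cycles. Kahn's algorithm with first-appearance tie-break.
topological_order <- function(edges) {
  nodes <- unique(c(edges$from, edges$to))
  indeg <- vapply(nodes, function(v) sum(edges$to == v), numeric(1))
  order_out <- character(0)
  active <- rep(TRUE, nrow(edges))
  while (length(nodes) > 0L) {
    ready <- nodes[indeg[nodes] == 0]
    if (length(ready) == 0L) abort("`paths` contain a directed cycle.")
    v <- ready[1]
    order_out <- c(order_out, v)
    out_edges <- active & edges$from == v
    for (w in edges$to[out_edges]) indeg[w] <- indeg[w] - 1
    active[out_edges] <- FALSE
    nodes <- setdiff(nodes, v)
  }
  order_out
}

#' Export a graph as DOT text and an edge-list table
#'
#' `graph_to_dot()` renders a `causal_graph` or `path_model` as a Graphviz
#' DOT digraph with coefficient edge labels and significance stars
#' (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05). `export_graph()`
#' additionally writes the DOT text and/or a CSV edge list
#' (`source,target,estimate,std_err,z,p`) to files.
#'
#' @param x A `causal_graph` or `path_model`.
#' @param dot_file,csv_file Optional output paths.
#' @return `graph_to_dot()`: a character scalar. `export_graph()`:
#'   invisibly, a list with the DOT text and the edge tibble.
#' @export
graph_to_dot <- function(x) {
  if (inherits(x, "causal_graph")) {
    nodes <- x$nodes
    edges <- x$edges
    pcol <- "p_value"
  } else {
    edges <- as_tibble(x)
    nodes <- attr(x, "nodes") %||% unique(c(edges$from, edges$to))
    pcol <- "p_value"
  }
  lines <- c("digraph causal {", "  rankdir=LR;",
             sprintf("  \"%s\";", nodes))
  if (nrow(edges) > 0L) {
    stars <- vapply(edges[[pcol]], sig_stars, character(1))
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%.3f%s\"];",
      edges$from, edges$to, edges$estimate, stars))
  }
  paste(c(lines, "}"), collapse = "\n")
}

sig_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

#' @rdname graph_to_dot
#' @export
export_graph <- function(x, dot_file = NULL, csv_file = NULL) {
  dot <- graph_to_dot(x)
  edges <- if (inherits(x, "causal_graph")) x$edges else as_tibble(x)
  out <- edges
  names(out)[names(out) == "from"] <- "source"
  names(out)[names(out) == "to"] <- "target"
  names(out)[names(out) == "p_value"] <- "p"
  if (!is.null(dot_file)) writeLines(dot, dot_file)
  if (!is.null(csv_file)) utils::write.csv(out, csv_file, row.names = FALSE)
  invisible(list(dot = dot, edges = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
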