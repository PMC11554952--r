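# Shared fixture builders; everything is generated in code under fixed seeds.

# Small importance table in long format.
toy_scores <- function(scores_by_method) {
  features <- paste0("f", seq_along(scores_by_method[[1]]))
  dplyr::bind_rows(lapply(names(scores_by_method), function(m) {
    tibble::tibble(method = m, feature = features,
                   score = scores_by_method[[m]])
  }))
}

# Random normalized importance table (entries already in [0, 1]).
rand_norm_tbl <- function(n_methods, p, seed) {
  withr::with_seed(seed, {
    toy_scores(setNames(
      lapply(seq_len(n_methods), function(i) runif(p)),
      paste0("m", seq_len(n_methods))
    ))
  })
}

# Random weight vector on the delta-lattice.
rand_lattice_weights <- function(n_methods, delta, seed) {
  m <- as.integer(round(1 / delta))
  withr::with_seed(seed, {
    cuts <- sort(sample(0:m, n_methods - 1, replace = TRUE))
    diff(c(0, cuts, m)) * delta
  })
}

# Chain coefficient matrix x1 -> x2 -> x3 with the given edge weights.
chain_B <- function(b21 = 1, b32 = 1) {
  B <- matrix(0, 3, 3)
  B[2, 1] <- b21
  B[3, 2] <- b32
  B
}

# Brute-force distance correlation: plain loops, no shared code with the
# package implementation.
dcor_bruteforce <- function(x, y) {
  n <- length(x)
  A <- matrix(0, n, n)
  B <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    A[i, j] <- abs(x[i] - x[j])
    B[i, j] <- abs(y[i] - y[j])
  }
  center <- function(M) {
    out <- matrix(0, n, n)
    gm <- mean(M)
    for (i in 1:n) for (j in 1:n) {
      out[i, j] <- M[i, j] - mean(M[i, ]) - mean(M[, j]) + gm
    }
    out
  }
  Ac <- center(A); Bc <- center(B)
  dcov2 <- sum(Ac * Bc) / n^2
  dvx <- sum(Ac * Ac) / n^2
  dvy <- sum(Bc * Bc) / n^2
  if (dvx * dvy <= 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvx * dvy))
}

# The six-path recursive model reported for the diabetes benchmark.
diabetes_paths <- function() {
  data.frame(from = c("GLU", "LTG", "TC", "LTG", "ABP", "BMI"),
             to   = c("LTG", "TC", "LDL", "Target", "Target", "Target"))
}
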