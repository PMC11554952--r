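# Seeded generators emulating the statistical structure the framework
# assumes: a tabular regression task with planted relevant features (and
# optionally near-duplicate collinear pairs), and linear non-Gaussian
# acyclic systems for the causal stage. All generators are bitwise
# deterministic under a fixed seed.

#' Simulate a regression dataset with planted relevant features
#'
#' Draws `p` standard-normal features, optionally makes some pairs
#' correlated (`x_j = rho * x_i + sqrt(1 - rho^2) * noise`, emulating
#' near-duplicate measurements such as step count vs step distance), and
#' builds the target as a linear combination of the relevant features plus
#' Gaussian noise.
#'
#' @param n,p Number of samples and features.
#' @param relevant Integer indices of the features that influence the target.
#' @param effects Effect size per relevant feature (recycled).
#' @param noise_sd Standard deviation of the additive Gaussian noise on the
#'   target (0 gives an exact linear target).
#' @param cor_pairs Optional data frame with columns `i`, `j`, `rho`: feature
#'   `j` is rebuilt as a `rho`-correlated copy of feature `i`.
#' @param seed Integer seed.
#' @return A tibble with feature columns `x1..xp` and target column `y`.
#'   The generating truth (arguments) is attached as attribute `"truth"`.
#' @examples
#' d <- sim_regression(n = 100, p = 5, relevant = c(1, 3),
#'                     effects = c(2, -1), seed = 42)
#' attr(d, "truth")$relevant
#' @export
sim_regression <- function(n = 150L, p = 16L, relevant = 1:3,
                           effects = 1, noise_sd = 1, cor_pairs = NULL,
                           seed = 0L) {
  if (n < 2L || p < 1L) abort("`n` and `p` must be positive (n >= 2).")
  if (length(relevant) > 0L &&
      (any(relevant < 1L) || any(relevant > p))) {
    abort("`relevant` indices must lie in [1, p].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")
  effects <- rep_len(effects, length(relevant))
  if (!all(is.finite(effects))) abort("`effects` must be finite.")
  gen <- withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    if (!is.null(cor_pairs)) {
      for (r in seq_len(nrow(cor_pairs))) {
        i <- cor_pairs$i[r]; j <- cor_pairs$j[r]; rho <- cor_pairs$rho[r]
        if (abs(rho) > 1) abort("`rho` must be in [-1, 1].")
        X[, j] <- rho * X[, i] + sqrt(1 - rho^2) * rnorm(n)
      }
    }
    y <- as.vector(X[, relevant, drop = FALSE] %*% effects) +
      rnorm(n, sd = noise_sd)
    list(X = X, y = y)
  })
  X <- gen$X
  y <- gen$y
  out <- as_tibble(as.data.frame(X), .name_repair = "minimal")
  names(out) <- paste0("x", seq_len(p))
  out$y <- y
  attr(out, "truth") <- list(relevant = relevant, effects = effects,
                             noise_sd = noise_sd, cor_pairs = cor_pairs,
                             seed = seed)
  out
}

#' Simulate a wearable-style health dataset
#'
#' A preset of [sim_regression()] shaped like a small wearable-device study:
#' 16 features, a handful of truly predictive ones, and two highly
#' correlated near-duplicate pairs (such as step number vs step distance at
#' r = 0.95) so the multicollinearity stage has something to find. The
#' target plays the role of a bounded health score.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return A tibble as from [sim_regression()].
#' @export
sim_wdlike <- function(n = 150L, seed = 0L) {
  sim_regression(
    n = n, p = 16L, relevant = c(1L, 3L, 5L, 7L),
    effects = c(1.5, 1.2, 0.8, 0.6), noise_sd = 1,
    cor_pairs = data.frame(i = c(1L, 5L), j = c(2L, 6L),
                           rho = c(0.95, 0.9)),
    seed = seed
  )
}

#' Simulate a linear non-Gaussian acyclic model
#'
#' Generates data from `x = B x + e` with strictly-triangular-under-some-
#' permutation coefficient matrix `B` and independent non-Gaussian noise,
#' the identifiability regime of LiNGAM-style causal discovery. Variables
#' are solved in topological order, and the hidden true order and `B` are
#' returned for recovery tests.
#'
#' @param B Square coefficient matrix; `B[i, j]` is the effect of variable j
#'   on variable i. Must be permutable to strict lower-triangular form
#'   (acyclic); otherwise an error.
#' @param n Number of samples.
#' @param noise `"uniform"` (variance-1 uniform) or `"laplace"`.
#' @param noise_scale Standard deviation of each noise term (recycled).
#' @param seed Integer seed.
#' @return A list: `data` (tibble `x1..xp`), `order` (true causal order,
#'   column names), `B` (the coefficient matrix used).
#' @examples
#' B <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)  # x2 = 2 x1 + e2
#' sim <- sim_lingam(B, n = 1000, seed = 7)
#' coef(lm(x2 ~ x1, sim$data))[2]
#' @export
sim_lingam <- function(B, n = 1000L, noise = c("uniform", "laplace"),
                       noise_scale = 1, seed = 0L) {
  noise <- match.arg(noise)
  B <- as.matrix(B)
  p <- nrow(B)
  if (ncol(B) != p) abort("`B` must be square.")
  topo <- b_topological_order(B)
  noise_scale <- rep_len(noise_scale, p)
  E <- withr::with_seed(seed, switch(noise,
    uniform = matrix(runif(n * p, -sqrt(3), sqrt(3)), n, p),
    laplace = matrix(rexp(n * p) - rexp(n * p), n, p) / sqrt(2)
  ))
  E <- sweep(E, 2L, noise_scale, "*")
  X <- matrix(0, n, p)
  for (i in topo) {
    X[, i] <- as.vector(X %*% B[i, ]) + E[, i]
  }
  colnames(X) <- paste0("x", seq_len(p))
  list(data = as_tibble(as.data.frame(X)),
       order = colnames(X)[topo], B = B)
}

# Internal: topological order of B (B[i, j] != 0 means j -> i); errors if
# cyclic.
b_topological_order <- function(B) {
  p <- nrow(B)
  remaining <- seq_len(p)
  topo <- integer(0)
  Bw <- B != 0
  while (length(remaining) > 0L) {
    src <- remaining[rowSums(Bw[remaining, remaining, drop = FALSE]) == 0]
    if (length(src) == 0L) abort("`B` is cyclic; no topological order exists.")
    topo <- c(topo, src[1])
    remaining <- setdiff(remaining, src[1])
  }
  topo
}

#' Load the open diabetes benchmark dataset
#'
#' Loads the classic 442-patient diabetes study (10 baseline variables and a
#' disease-progression score one year after baseline) from a tab-delimited
#' file; by default the copy bundled with the package. Columns are renamed
#' to the conventional labels: average blood pressure `ABP`; serum
#' measurements `TC` (total cholesterol), `LDL`, `HDL`, `TCH`
#' (total cholesterol / HDL), `LTG` (log serum triglycerides), `GLU` (blood
#' glucose); and `Target`, the progression outcome.
#'
#' @param path Optional path to a tab-delimited copy of the dataset (with
#'   either the original `AGE ... S1..S6 Y` header or already-final names).
#' @return A tibble with 442 rows and columns `age`, `sex`, `BMI`, `ABP`,
#'   `TC`, `LDL`, `HDL`, `TCH`, `LTG`, `GLU`, `Target`.
#' @export
load_diabetes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "diabetes.tsv", package = "wtsfs")
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- utils::read.delim(path, check.names = FALSE)
  rename_map <- c(age = "age", sex = "sex", bmi = "BMI", bp = "ABP",
                  s1 = "TC", s2 = "LDL", s3 = "HDL", s4 = "TCH",
                  s5 = "LTG", s6 = "GLU", y = "Target")
  nm <- tolower(names(raw))
  final <- c("age", "sex", "BMI", "ABP", "TC", "LDL", "HDL", "TCH",
             "LTG", "GLU", "Target")
  if (all(nm %in% names(rename_map))) {
    names(raw) <- unname(rename_map[nm])
  }
  missing <- setdiff(final, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("diabetes file lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  raw <- raw[final]
  if (nrow(raw) != 442L) {
    abort(sprintf("expected 442 patients, found %d rows.", nrow(raw)))
  }
  if (anyNA(raw)) abort("diabetes data must not contain missing values.")
  as_tibble(raw)
}
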