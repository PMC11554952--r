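#' Sample distance correlation
#'
#' Computes the sample distance correlation between two numeric vectors using
#' the double-centered Euclidean distance matrices (the V-statistic form).
#' Distance correlation is zero if and only if the two variables are
#' independent (in the population), and lies in \[0, 1\]; it detects nonlinear
#' as well as linear association, which is why it serves both as a feature
#' screen and as the independence measure inside the causal-ordering step.
#'
#' @param x,y Numeric vectors of equal length (at least 2 observations).
#' @return A single number in \[0, 1\].
#' @examples
#' x <- rnorm(50)
#' distance_cor(x, x)        # exactly 1
#' distance_cor(x, x^2)      # picks up the nonlinear link
#' @export
distance_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2L) abort("need at least 2 observations.")
  if (anyNA(x) || anyNA(y)) abort("missing values not allowed.")
  A <- dcenter(abs(outer(x, x, "-")))
  B <- dcenter(abs(outer(y, y, "-")))
  dcov2 <- mean(A * B)
  dvar_x <- mean(A * A)
  dvar_y <- mean(B * B)
  denom <- sqrt(dvar_x * dvar_y)
  if (denom <= 0) return(0)
  # clamp tiny negative round-off before the square root
  sqrt(max(dcov2, 0) / denom)
}

# Internal: double-center a distance matrix.
dcenter <- function(D) {
  rm <- rowMeans(D)
  D - outer(rm, rm, "+") + mean(D)
}
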