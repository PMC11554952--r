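# Internal: validate a samples-by-variables data frame and split off the target.
#
# Every user-facing function funnels through here, so the contract (numeric,
# complete, n >= 3, unique feature names disjoint from the target) is enforced
# exactly once.
as_fs_data <- function(data, target, min_n = 3L) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (samples in rows, variables in columns).")
  }
  if (!is.character(target) || length(target) != 1L || !nzchar(target)) {
    abort("`target` must be a single column name.")
  }
  if (!target %in% names(data)) {
    abort(sprintf("target column '%s' not found in `data`.", target))
  }
  feature_names <- setdiff(names(data), target)
  if (length(feature_names) < 1L) {
    abort("`data` must contain at least one feature column besides the target.")
  }
  if (anyDuplicated(names(data))) {
    abort("column names of `data` must be unique.")
  }
  X <- as.matrix(data[feature_names])
  y <- data[[target]]
  if (!is.numeric(X) || !is.numeric(y)) {
    abort("all feature columns and the target must be numeric.")
  }
  if (anyNA(X) || anyNA(y) || !all(is.finite(X)) || !all(is.finite(y))) {
    abort("`data` must not contain missing or non-finite values.")
  }
  if (nrow(X) < min_n) {
    abort(sprintf("need at least %d samples, got %d.", min_n, nrow(X)))
  }
  list(X = X, y = y, feature_names = feature_names, target_name = target)
}

# Internal: error if any named column is constant.
check_nonconstant <- function(X, what = "feature") {
  sds <- apply(X, 2L, stats::sd)
  bad <- colnames(X)[sds == 0]
  if (length(bad) > 0L) {
    abort(sprintf("%s column(s) with zero variance: %s",
                  what, paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

# Internal: min-max rescale a vector to [0, 1]; constant vectors map to 0.
minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# Internal: min-max scale every column of a matrix or data frame.
minmax_scale <- function(X) {
  out <- apply(X, 2L, minmax)
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(X), dimnames = dimnames(X))
  out
}
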