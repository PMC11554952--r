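test_that("regression_metrics matches hand-computed values", {
  m <- regression_metrics(c(0, 1), c(0.5, 0.5))
  expect_equal(m$mse, 0.25)
  expect_equal(m$rmse, 0.5)
  expect_equal(m$mae, 0.5)
  expect_equal(m$r2, 0)
  expect_equal(m$ev, 0)
  expect_equal(m$rmse, sqrt(m$mse))
})

test_that("a noiseless linear target evaluates to a perfect fit", {
  d <- sim_regression(n = 60, p = 4, relevant = 1:2, effects = c(2, -1),
                      noise_sd = 0, seed = 3)
  m <- evaluate_subset(d, "y", c("x1", "x2"), seed = 1)
  expect_equal(m$mse, 0, tolerance = 1e-20)
  expect_equal(m$r2, 1, tolerance = 1e-10)
  expect_equal(m$ev, 1, tolerance = 1e-10)
})

test_that("the evaluation cache memoizes by subset and counts hits", {
  d <- sim_regression(n = 50, p = 3, relevant = 1, effects = 2, seed = 5)
  cache <- new_eval_cache()
  m1 <- evaluate_subset(d, "y", c("x2", "x1"), seed = 7, cache = cache)
  expect_equal(cache$hits, 0L)
  # same subset in different order hits the canonical key
  m2 <- evaluate_subset(d, "y", c("x1", "x2"), seed = 7, cache = cache)
  expect_equal(cache$hits, 1L)
  expect_identical(m1, m2)
  # caching must not change values
  m3 <- evaluate_subset(d, "y", c("x1", "x2"), seed = 7)
  expect_identical(m1, m3)
})

test_that("weight moves transfer one delta unit and preserve the simplex", {
  mv <- enumerate_weight_moves(c(0.5, 0.5), 0.5)
  expect_setequal(lapply(mv, as.numeric), list(c(1, 0), c(0, 1)))
  mv3 <- enumerate_weight_moves(c(1, 0, 0), 0.5)
  expect_setequal(lapply(mv3, as.numeric),
                  list(c(0.5, 0.5, 0), c(0.5, 0, 0.5)))
  for (w in enumerate_weight_moves(c(0.2, 0.3, 0.5), 0.1)) {
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
  expect_error(enumerate_weight_moves(c(0.3, 0.7), 0.2), "lattice")
  expect_error(enumerate_weight_moves(c(0.5, 0.5), 0.3), "integer")
})

test_that("the full lattice enumeration covers every composition once", {
  lat <- enumerate_weight_lattice(3, 0.5)
  expect_length(lat, 6L)  # compositions of 2 into 3 parts
  expect_true(all(vapply(lat, sum, numeric(1)) == 1))
  expect_length(enumerate_weight_lattice(2, 0.25), 5L)
})

test_that("a single method forces W* = 1 and reduces to a k-search", {
  d <- sim_regression(n = 80, p = 4, relevant = 1:2, effects = c(3, 2),
                      noise_sd = 0.3, seed = 13)
  imp <- score_features(d, "y", methods = "pearson", seed = 1)
  fit <- optimize_weights(d, "y", importance = imp, delta = 0.5, seed = 1)
  expect_equal(unname(fit$w_star), 1)
  expect_equal(length(fit$selected), fit$k_star)
})

test_that("greedy with vertex restarts equals exhaustive search on small lattices", {
  for (seed in c(2, 17)) {
    d <- sim_regression(n = 70, p = 5, relevant = c(1, 4),
                        effects = c(2, 1.5), noise_sd = 0.5, seed = seed)
    imp <- score_features(d, "y", methods = c("pearson", "distance", "lasso"),
                          seed = seed)
    gr <- optimize_weights(d, "y", importance = imp, delta = 0.5,
                           seed = seed, restarts = "vertices")
    ex <- optimize_weights(d, "y", importance = imp, delta = 0.5,
                           seed = seed, search = "exhaustive")
    expect_equal(gr$w_star, ex$w_star)
    expect_equal(gr$k_star, ex$k_star)
    expect_equal(gr$metrics, ex$metrics)
  }
})

test_that("optimization is deterministic under a fixed seed", {
  d <- sim_regression(n = 60, p = 4, relevant = 1, effects = 2, seed = 23)
  imp <- score_features(d, "y", methods = c("pearson", "distance"), seed = 23)
  f1 <- optimize_weights(d, "y", importance = imp, delta = 0.5, seed = 23)
  f2 <- optimize_weights(d, "y", importance = imp, delta = 0.5, seed = 23)
  expect_identical(f1$w_star, f2$w_star)
  expect_identical(f1$metrics, f2$metrics)
})

test_that("the optimum never loses to the equal-weight start at any k", {
  d <- sim_regression(n = 90, p = 6, relevant = c(1, 3), effects = c(2, 1),
                      noise_sd = 0.5, seed = 29)
  imp <- score_features(d, "y", methods = c("pearson", "distance"), seed = 29)
  fit <- optimize_weights(d, "y", importance = imp, delta = 0.5, seed = 29)
  normed <- suppressWarnings(normalize_scores(imp))
  eq <- c(0.5, 0.5)
  for (k in 1:6) {
    sub <- select_top_k(compute_wts(normed, eq), k)
    m <- evaluate_subset(d, "y", sub, seed = 29)
    expect_lte(fit$metrics$mse, m$mse)
  }
  # baseline table carries the equal-weight row for the same comparison
  eqrow <- fit$baselines[fit$baselines$method == "equal_weight", ]
  expect_lte(fit$metrics$mse, eqrow$mse)
})

test_that("the optimizer recovers the one informative method", {
  # method A scores the truly predictive features highest; method B prefers
  # pure-noise columns, so all lattice weight should move to A
  d <- sim_regression(n = 150, p = 6, relevant = 1:2, effects = c(3, 2),
                      noise_sd = 0.3, seed = 37)
  good <- score_pearson(d, "y")
  bad <- good |> dplyr::mutate(score = max(score) - score)
  imp <- dplyr::bind_rows(
    dplyr::mutate(good, method = "informative"),
    dplyr::mutate(bad, method = "misleading")
  )[c("method", "feature", "score")]
  fit <- optimize_weights(d, "y", importance = imp, delta = 0.25, seed = 37,
                          k_range = 1:4)
  expect_gt(fit$w_star["informative"], 0.5)
  expect_true(all(c("x1", "x2") %in% fit$selected))
  # and it performs at least as well as trusting the informative method alone
  inf_best <- fit$baselines[fit$baselines$method == "informative", ]
  expect_lte(fit$metrics$mse, inf_best$mse)
})

test_that("tidy and glance expose the selection and its metrics", {
  d <- sim_regression(n = 60, p = 4, relevant = 1, effects = 2, seed = 41)
  imp <- score_features(d, "y", methods = c("pearson", "distance"), seed = 41)
  fit <- optimize_weights(d, "y", importance = imp, delta = 0.5, seed = 41)
  td <- tidy(fit)
  expect_equal(sum(td$selected), fit$k_star)
  expect_equal(td$feature[td$selected], fit$selected)
  gl <- glance(fit)
  expect_equal(gl$mse, fit$metrics$mse)
  expect_equal(gl$k_star, fit$k_star)
})
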