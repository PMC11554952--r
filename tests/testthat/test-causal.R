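test_that("ordering a single variable returns it unchanged", {
  d <- tibble::tibble(x1 = rnorm(10))
  expect_equal(lingam_order(d), "x1")
})

test_that("a non-Gaussian pair is oriented correctly", {
  B <- matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE)  # x2 = 2 x1 + e
  sim <- sim_lingam(B, n = 2000, noise = "uniform", seed = 101)
  expect_equal(lingam_order(sim$data), c("x1", "x2"))
})

test_that("a three-variable chain is recovered across seeds", {
  hits <- vapply(1:5, function(s) {
    sim <- sim_lingam(chain_B(1, 1), n = 2000, seed = 200 + s)
    identical(lingam_order(sim$data, seed = s), sim$order)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("edge estimation recovers coefficients and prunes absent edges", {
  sim <- sim_lingam(chain_B(2, -1.5), n = 5000, seed = 77)
  g <- lingam_fit(sim$data, order = sim$order)
  expect_s3_class(g, "causal_graph")
  e12 <- g$edges[g$edges$from == "x1" & g$edges$to == "x2", ]
  e23 <- g$edges[g$edges$from == "x2" & g$edges$to == "x3", ]
  expect_equal(e12$estimate, 2, tolerance = 0.05)
  expect_equal(e23$estimate, -1.5, tolerance = 0.05)
  # the skipped x1 -> x3 edge is conditionally absent; usually pruned
  expect_lte(nrow(g$edges), 3L)
})

test_that("independent variables yield edge retention near the alpha level", {
  retained <- 0L
  tested <- 0L
  for (s in 1:10) {
    sim <- sim_lingam(matrix(0, 4, 4), n = 400, seed = 300 + s)
    g <- lingam_fit(sim$data, order = paste0("x", 1:4), alpha = 0.05)
    retained <- retained + nrow(g$edges)
    tested <- tested + 6L
  }
  expect_lte(retained / tested, 0.15)  # ~5% type-I error, with slack
})

test_that("every fitted graph is acyclic along its causal order", {
  for (s in 1:3) {
    sim <- sim_lingam(chain_B(1, 0.8), n = 1000, seed = 400 + s)
    g <- lingam_fit(sim$data, order = sim$order)
    pos <- match(g$edges$from, g$causal_order) <
      match(g$edges$to, g$causal_order)
    expect_true(all(pos))
  }
})

test_that("a single path matches the OLS slope and t statistic", {
  d <- withr::with_seed(55, {
    x <- runif(400)
    tibble::tibble(x = x, y = 2 * x + 0.3 * rnorm(400))
  })
  pm <- fit_path_model(d, data.frame(from = "x", to = "y"), scale = "none")
  ols <- summary(lm(y ~ x, d))$coefficients["x", ]
  expect_equal(pm$estimate, unname(ols["Estimate"]), tolerance = 1e-9)
  expect_equal(pm$z, unname(ols["t value"]), tolerance = 0.02)
})

test_that("zero residual variance is a singular-model error", {
  d <- tibble::tibble(x = rnorm(50))
  d$y <- d$x
  expect_error(fit_path_model(d, data.frame(from = "x", to = "y")),
               "singular")
})

test_that("self-loops and cycles are rejected", {
  d <- tibble::tibble(a = rnorm(50), b = rnorm(50))
  expect_error(fit_path_model(d, data.frame(from = "a", to = "a")),
               "differ")
  cyc <- data.frame(from = c("a", "b"), to = c("b", "a"))
  expect_error(fit_path_model(d, cyc), "cycle")
})

test_that("z and p are mutually consistent and scale-invariant", {
  d <- load_diabetes()
  pm <- fit_path_model(d, diabetes_paths())
  expect_equal(pm$p_value, 2 * pnorm(-abs(pm$z)), tolerance = 1e-9)
  expect_equal(pm$z, pm$estimate / pm$std_err, tolerance = 1e-6)
  pm_std <- fit_path_model(d, diabetes_paths(), scale = "standardize")
  expect_equal(pm$z, pm_std$z, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(pm$estimate, pm_std$estimate)))
})

test_that("the six-path diabetes model exports six rows and valid DOT", {
  d <- load_diabetes()
  pm <- fit_path_model(d, diabetes_paths())
  expect_equal(nrow(pm), 6L)
  tmp_csv <- withr::local_tempfile(fileext = ".csv")
  tmp_dot <- withr::local_tempfile(fileext = ".dot")
  out <- export_graph(pm, dot_file = tmp_dot, csv_file = tmp_csv)
  back <- utils::read.csv(tmp_csv)
  expect_equal(nrow(back), 6L)
  expect_equal(back$estimate, pm$estimate, tolerance = 1e-12)
  expect_equal(names(back), c("source", "target", "estimate", "std_err",
                              "z", "p"))
  dot <- readLines(tmp_dot)
  expect_equal(dot[1], "digraph causal {")
  expect_equal(sum(grepl("->", dot, fixed = TRUE)), 6L)
  expect_true(all(grepl("\\*\\*\\*", dot[grepl("->", dot)])))  # all p < .001
})

test_that("an empty graph exports nodes only", {
  g <- structure(list(nodes = c("a", "b"), causal_order = c("a", "b"),
                      edges = tibble::tibble(from = character(),
                                             to = character(),
                                             estimate = numeric(),
                                             std_err = numeric(),
                                             p_value = numeric()),
                      alpha = 0.05),
                 class = "causal_graph")
  dot <- graph_to_dot(g)
  expect_match(dot, "\"a\";")
  expect_false(grepl("->", dot, fixed = TRUE))
})
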