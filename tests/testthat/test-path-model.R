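test_that("single predictor: path coefficient equals the simple correlation", {
  set.seed(2)
  d <- data.frame(x = rnorm(25))
  d$y <- 0.6 * d$x + rnorm(25)
  f <- fit_standardized(zscore_matrix(d), "y", "x")
  expect_equal(unname(f$direct), cor(d$x, d$y), tolerance = 1e-12)
  expect_equal(f$r2, cor(d$x, d$y)^2, tolerance = 1e-12)
})

test_that("two-predictor fit matches the hand-solved normal equations", {
  v <- c("y", "x1", "x2")
  R <- named_corr(v, 1, 0.7, 0.6, 0.7, 1, 0.5, 0.6, 0.5, 1)
  d <- make_exact_corr_data(40, R, seed = 5)
  f <- fit_standardized(zscore_matrix(d), "y", c("x1", "x2"))
  # P1 = (0.7 - 0.5*0.6)/(1 - 0.25), P2 = (0.6 - 0.5*0.7)/0.75
  expect_equal(unname(f$direct), c(0.53333333, 0.33333333), tolerance = 1e-8)
  pr <- decompose_effects(zscore_matrix(d), "y", c("x1", "x2"))
  expect_equal(unname(pr$indirect["x1", "x2"]), 0.5 * 1 / 3, tolerance = 1e-8)
  expect_equal(unname(pr$total["x1"]), 0.7, tolerance = 1e-8)
  expect_equal(unname(pr$total["x2"]), 0.6, tolerance = 1e-8)
})

test_that("solver matches brute-force least squares on random instances", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    p <- sample(1:5, 1)
    d <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(d) <- paste0("x", seq_len(p))
    d$y <- rowSums(d * runif(p, -1, 1)) + rnorm(n)
    preds <- paste0("x", seq_len(p))
    f <- fit_standardized(zscore_matrix(d), "y", preds)
    expect_equal(f$direct, lm_standardized(d, "y", preds), tolerance = 1e-8)
  }
})

test_that("full-model decomposition reconstructs every simple correlation", {
  tab <- load_fixture("survey")
  paths <- run_k_path_models(tab, eliminate = FALSE)
  for (pr in paths) {
    expect_equal(unname(pr$total), unname(pr$r_xy), tolerance = 1e-8)
    expect_equal(pr$residue^2 + pr$r2, 1, tolerance = 1e-12)
  }
  set.seed(23)
  for (i in 1:100) {
    n <- sample(15:40, 1)
    p <- sample(2:5, 1)
    d <- as.data.frame(matrix(rnorm(n * (p + 1)), n))
    names(d) <- c("y", paste0("x", seq_len(p)))
    pr <- decompose_effects(zscore_matrix(d), "y", paste0("x", seq_len(p)))
    expect_equal(unname(pr$total), unname(pr$r_xy), tolerance = 1e-8)
    expect_equal(pr$residue, sqrt(1 - pr$r2), tolerance = 1e-12)
  }
})

test_that("coefficients are invariant under predictor permutation", {
  set.seed(31)
  d <- as.data.frame(matrix(rnorm(30 * 4), 30, 4))
  names(d) <- c("y", "a", "b", "c")
  z <- zscore_matrix(d)
  f1 <- fit_standardized(z, "y", c("a", "b", "c"))
  f2 <- fit_standardized(z, "y", c("c", "a", "b"))
  expect_equal(f1$direct[c("c", "a", "b")], f2$direct, tolerance = 1e-12)
})

test_that("collinear predictor sets raise a named error", {
  set.seed(41)
  d <- data.frame(y = rnorm(20), x1 = rnorm(20))
  d$x2 <- d$x1  # exact duplicate
  expect_error(fit_standardized(zscore_matrix(d), "y", c("x1", "x2")),
               "collinearity")
  expect_error(fit_standardized(zscore_matrix(d), "y", "y"), "response")
  expect_error(fit_standardized(zscore_matrix(d[1:3, ]), "y", c("x1", "x2")),
               "too small")
})

test_that("backward elimination drops pure-noise predictors and keeps signal", {
  set.seed(42)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- 0.8 * d$x1 + rnorm(n, sd = 0.6)
  z <- zscore_matrix(d)
  bk <- backward_eliminate(z, "y", c("x1", "x2"))
  expect_equal(bk$retained, "x1")
  expect_equal(bk$trace$variable, "x2")
  # oracle: x2's coefficient is insignificant in the full ordinary fit
  full <- summary(lm(y ~ x1 + x2, d))$coefficients
  expect_gt(full["x2", 4], 0.05)
  expect_lt(full["x1", 4], 0.05)
  # boundary: alpha_remove = 1 never removes anything
  bk2 <- backward_eliminate(z, "y", c("x1", "x2"), alpha_remove = 1)
  expect_equal(bk2$retained, c("x1", "x2"))
  expect_equal(nrow(bk2$trace), 0)
})

test_that("eliminating every predictor yields the empty model with residue 1", {
  set.seed(43)
  d <- data.frame(y = rnorm(30), x1 = rnorm(30), x2 = rnorm(30))
  z <- zscore_matrix(d)
  expect_warning(bk <- backward_eliminate(z, "y", c("x1", "x2"),
                                          alpha_remove = 1e-12), "eliminated")
  expect_length(bk$retained, 0)
  pr <- decompose_effects(z, "y", bk$retained)
  expect_equal(pr$residue, 1)
  expect_equal(pr$r2, 0)
})

test_that("survey models fit the published predictor sets", {
  tab <- load_fixture("survey")
  paths <- suppressWarnings(run_k_path_models(tab))
  expect_named(paths, c("wsk", "nek", "ek"))
  for (pr in paths) expect_lte(length(pr$predictors), 8)
  # with 16 rows and 8 predictors the fit warns about fragile df
  expect_warning(run_k_path_models(tab, eliminate = FALSE), "degrees of freedom")
  cmp <- compare_path_table(paths$wsk, load_fixture("path_wsK"))
  expect_true(all(c("direct_cc", "simple_r", "direct_P") %in% names(cmp)))
})

test_that("DOT export writes a well-formed weighted path diagram", {
  tab <- load_fixture("survey")
  z <- zscore_matrix(tab)
  pr <- decompose_effects(z, "wsk", c("nek", "ek", "som"))
  f <- withr::local_tempfile(fileext = ".dot")
  export_path_diagram(pr, f)
  dot <- readLines(f)
  expect_match(dot[1], "^digraph")
  expect_identical(dot[length(dot)], "}")
  expect_equal(sum(grepl("style=dashed", dot)), 3)   # one direct edge each
  expect_equal(sum(grepl("dir=both", dot)),
               sum(abs(pr$r_xx[upper.tri(pr$r_xx)]) >= 0.5))
  expect_equal(sum(grepl("^  e ->", dot)), 1)        # residue node attached
  # single predictor: predictor, response, e; 2 edges
  pr1 <- decompose_effects(z, "wsk", "nek")
  export_path_diagram(pr1, f)
  expect_equal(sum(grepl("->", readLines(f))), 2)
  # empty retained set: response and e only
  pr0 <- decompose_effects(z, "wsk", character(0))
  export_path_diagram(pr0, f)
  expect_equal(sum(grepl("->", readLines(f))), 1)
  expect_error(export_path_diagram(pr, "/nonexistent-dir/x.dot"), "I/O error")
})
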