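# Evaluation statistics.

test_that("adjusted R-squared follows its closed form", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(r2_adj(y, y, p = 2), 1.0)
  # R2 = 0.8, n = 101, p = 10 -> 1 - 0.2*100/90
  set.seed(2)
  n <- 101
  # construct a prediction vector with squared correlation exactly 0.8
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))            # orthogonalize
  yh <- x
  yy <- sqrt(0.8) * x / sd(x) + sqrt(0.2) * e / sd(e)
  r2 <- cor(yy, yh)^2
  expect_equal(r2, 0.8, tolerance = 1e-10)
  expect_equal(r2_adj(yy, yh, p = 10), 1 - 0.2 * 100 / 90,
               tolerance = 1e-4)
  expect_equal(r2_adj(yy, yh, p = 10), 0.7778, tolerance = 1e-4)
  # p = 0 reduces to plain R2
  expect_equal(r2_adj(yy, yh, p = 0), r2, tolerance = 1e-12)
  expect_error(r2_adj(1:3, 1:3, p = 2), "n > p")
})

test_that("q2_ext, MAE and RMSE match hand arithmetic", {
  y <- c(1, 2, 3, 4)
  expect_equal(q2_ext(y, y), 1)
  expect_equal(mae(y, y), 0)
  expect_equal(rmse(y, y), 0)
  expect_equal(mae(c(0, 0), c(1, -1)), 1)
  expect_equal(rmse(c(0, 0), c(1, -1)), 1)
  expect_equal(mae(c(0, 0), c(0, 2)), 1)
  expect_equal(rmse(c(0, 0), c(0, 2)), sqrt(2))
  expect_gte(rmse(y, y + rnorm(4)), mae(y, y + rnorm(4)))
  expect_error(q2_ext(c(2, 2, 2), c(1, 2, 3)), "zero-variance")
  # translation invariance
  set.seed(12)
  yh <- y + rnorm(4, 0, 0.3)
  expect_equal(q2_ext(y, yh), q2_ext(y + 10, yh + 10))
  expect_equal(mae(y, yh), mae(y + 10, yh + 10))
})

test_that("cross-validated q2 behaves at its two extremes", {
  # memorizer on noiseless deterministic data: near-perfect q2
  set.seed(31)
  x <- matrix(runif(400, -2, 2), 200, 2)
  y <- sin(x[, 1]) + 0.5 * x[, 2]
  r <- q2_cv(x, y, learner_spec("knn", k = 1), folds = 10, seed = 1)
  expect_gte(r$q2, 0.9)
  expect_lte(r$q2, 1)
  expect_equal(r$press, sum((y - r$predictions)^2))
  # PRESS = SST exactly gives 0 by the formula
  expect_equal((r$sst - r$sst) / r$sst, 0)
})

test_that("q2 of a mean-only predictor is close to zero", {
  register_learner("meanonly",
    fit = function(x, y, hyper, seed) mean(y),
    predict = function(state, x) rep(state, nrow(x)),
    defaults = list())
  set.seed(41)
  x <- matrix(rnorm(1000), 1000, 1)
  y <- rnorm(1000)
  r <- q2_cv(x, y, learner_spec("meanonly"), folds = 10, seed = 2)
  expect_lt(abs(r$q2), 0.05)
})

test_that("Wilcoxon comparison matches exact enumeration and edge cases", {
  expect_warning(p <- wilcoxon_compare(rep(1, 10), rep(1, 10)), "zero")
  expect_equal(p, 1)
  set.seed(51)
  for (rep_ in 1:5) {
    n <- 10
    b <- runif(n, 1, 2)
    a <- b + runif(n, -0.9, 0.9)         # continuous: no ties, no zeros
    p_pkg <- wilcoxon_compare(a, b)
    p_oracle <- oracle_wilcoxon_exact(a - b)
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
  }
  # uniformly better model is extremely significant
  set.seed(52)
  b <- runif(50, 1, 2)
  expect_lt(wilcoxon_compare(b - 0.5, b), 1e-6)
})

test_that("metrics_report assembles consistent flags", {
  set.seed(61)
  ytr <- rnorm(50, 3); yte <- rnorm(30, 3)
  rep_ <- metrics_report(ytr, ytr + rnorm(50, 0, 0.1),
                         yte, yte + rnorm(30, 0, 0.1), p = 3, q2 = 0.8)
  expect_s3_class(rep_, "metrics_report")
  expect_lte(rep_$r2_adj, rep_$r2)
  expect_gte(rep_$rmse_test, rep_$mae_test)
  expect_true(rep_$acceptable_q2)
  expect_identical(rep_$overfit, rep_$r2_adj - rep_$q2_ext > 0.3)
})
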