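# Sensitivity importance, fragment alerts, stepwise deltas, scaffolds.

# a trivial linear "regressor" honoring the predict(model, newdata) contract
linear_model <- function(coefs) {
  structure(list(coefs = coefs), class = "test_linear")
}
predict.test_linear <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefs)
}
registerS3method("predict", "test_linear", predict.test_linear)

test_that("sensitivity importance tracks squared coefficients", {
  set.seed(91)
  X <- cbind(x1 = runif(200, -1, 1), x2 = runif(200, -1, 1),
             x3 = runif(200, -1, 1))
  # y = 2 x1 + x2; x3 ignored
  m <- linear_model(c(2, 1, 0))
  imp <- sensitivity_1d(m, X, levels = 7)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_equal(unname(imp["x3"]), 0)
  # ranges are equal so importance ratio = (2/1)^2 = 4 up to range jitter
  expect_equal(unname(imp["x1"] / imp["x2"]), 4, tolerance = 0.05)
  # invariant to affine rescaling of the response
  m2 <- linear_model(c(2, 1, 0) * 7)
  expect_equal(imp, sensitivity_1d(m2, X, levels = 7), tolerance = 1e-12)
})

test_that("fragment contribution applies the strict-majority sign rule", {
  bits <- c(1, 1, 1, 1, 1, 1, 1, 0, 0)
  act <- c(4, 5, 3.2, 3.8, 6, 1, 2, 9, 9)
  fc <- fragment_contribution(bits, act, threshold = 3)
  expect_equal(fc$count_high, 5)
  expect_equal(fc$count_low, 2)
  expect_equal(fc$sign, "positive")
  expect_equal(fc$count_high + fc$count_low, fc$n_with_fragment)
  tie <- fragment_contribution(rep(1, 6), c(1, 2, 2, 4, 5, 6), threshold = 3)
  expect_equal(tie$sign, "undetermined")
  neg <- fragment_contribution(c(1, 1, 1, 0), c(1, 1, 4, 9), threshold = 3)
  expect_equal(neg$sign, "negative")
  expect_warning(expect_null(
    fragment_contribution(rep(0, 5), rnorm(5))), "no molecule")
})

test_that("stepwise adjusted-R2 delta matches an OLS oracle", {
  set.seed(101)
  n <- 200
  base <- cbind(b1 = rnorm(n), b2 = rnorm(n))
  y <- base %*% c(1, -1) + rnorm(n, 0, 0.5)
  # duplicate of a base column can only lose adjusted R2
  dup <- stepwise_r2adj_delta(base, base[, 1], y)
  expect_lte(dup$delta, 0)
  expect_true(dup$collinear)
  # oracle check via lm()
  cand <- rnorm(n)
  got <- stepwise_r2adj_delta(base, cand, y)
  s0 <- summary(lm(y ~ base))$adj.r.squared
  s1 <- summary(lm(y ~ base + cand))$adj.r.squared
  expect_equal(got$delta, s1 - s0, tolerance = 1e-10)
  # the activity itself as candidate is a perfect predictor
  perf <- stepwise_r2adj_delta(base, y, y)
  expect_gt(perf$delta, 0)
  expect_equal(perf$r2adj_full, 1, tolerance = 1e-10)
})

test_that("pure-noise candidates move adjusted R2 only marginally", {
  set.seed(111)
  n <- 500
  base <- cbind(b1 = rnorm(n))
  y <- base[, 1] + rnorm(n)
  deltas <- vapply(1:40, function(i)
    stepwise_r2adj_delta(base, rnorm(n), y)$delta, 0)
  expect_gte(mean(abs(deltas) < 0.01), 0.95)
})

test_that("scaffold table honours threshold, frequency rule and loop oracle", {
  mols <- data.frame(
    id = paste0("m", 1:8),
    smiles = c("Cc1ccccc1", "CCc1ccccc1", "c1ccccc1O",   # benzene frames
               "CC1CCCCC1",                              # cyclohexane
               "CCCC", "CCCCC",                          # acyclic
               "Cc1ccncc1", "c1ccncc1"),                 # pyridine frames
    stringsAsFactors = FALSE)
  split <- structure(list(train_ids = paste0("m", 1:4),
                          test_ids = paste0("m", 5:8),
                          seed = 1, test_fraction = 0.5, n_bins = 2),
                     class = "dataset_split")
  err <- c(m1 = 2, m2 = 1.5, m3 = 1.2, m4 = 3, m5 = 2, m7 = 1.4, m8 = 1.1)
  tab <- error_scaffold_table(mols, split, err, mae_threshold = 1)
  benzene <- canonical_smiles("c1ccccc1")
  pyridine <- canonical_smiles("c1ccncc1")
  expect_equal(tab$scaffold[1], benzene)
  expect_equal(tab$frequency[1], 3L)
  expect_true(pyridine %in% tab$scaffold)
  # cyclohexane appears once among large errors -> excluded by the >= 2 rule
  expect_false(canonical_smiles("C1CCCCC1") %in% tab$scaffold)
  # per-split membership counts by explicit loop
  frames <- murcko_framework(mols$smiles)
  names(frames) <- mols$id
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$n_train[i],
                 sum(frames[split$train_ids] == tab$scaffold[i]))
    expect_equal(tab$n_test[i],
                 sum(frames[split$test_ids] == tab$scaffold[i]))
  }
  # frequencies cannot exceed the number of selected molecules
  expect_lte(sum(tab$frequency), sum(err > 1))
  # empty selection gives an empty report
  none <- error_scaffold_table(mols, split, c(m1 = 0.1), mae_threshold = 1)
  expect_equal(nrow(none), 0L)
})
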