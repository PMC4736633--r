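# Chi-squared / Cramer's V feature ranking.

test_that("discretize produces balanced bins and collapses degenerate input", {
  b <- discretize(1:100, 4)
  expect_equal(unname(table(b)), rep(25L, 4), ignore_attr = TRUE)
  expect_equal(sort(unique(b)), 0:3)
  # binary input keeps its native 2 levels whatever n_bins says
  bb <- discretize(rep(c(0, 1), 50), 10)
  expect_equal(attr(bb, "n_bins"), 2L)
  expect_warning(discretize(rep(1, 10), 3), "constant")
  # equal-width histogram agrees with hist() on a normal sample
  set.seed(9)
  v <- rnorm(10000)
  ew <- discretize(v, 10, strategy = "equal_width")
  h <- hist(v, breaks = seq(min(v), max(v), length.out = 11), plot = FALSE)
  expect_equal(unname(as.vector(table(ew))), h$counts)
  cnt <- h$counts
  peak <- which.max(cnt)
  expect_true(all(diff(cnt[seq_len(peak)]) >= 0))
  expect_true(all(diff(cnt[peak:length(cnt)]) <= 0))
})

test_that("chi-squared statistic matches direct evaluation", {
  expect_equal(as.numeric(chi2_stat(matrix(25, 2, 2))), 0)
  expect_equal(as.numeric(chi2_stat(matrix(c(50, 0, 0, 50), 2))), 100)
  expect_equal(as.numeric(chi2_stat(matrix(c(10, 20, 20, 10), 2))),
               20 / 3, tolerance = 1e-3)
  # random tables against the loop oracle
  set.seed(101)
  for (i in 1:200) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    O <- matrix(rpois(r * c, 8) + 1, r, c)
    expect_equal(as.numeric(chi2_stat(O)), oracle_chi2(O),
                 tolerance = 1e-10)
  }
})

test_that("chi-squared is symmetric under transposition", {
  set.seed(7)
  O <- matrix(rpois(12, 6) + 1, 3, 4)
  expect_equal(as.numeric(chi2_stat(O)), as.numeric(chi2_stat(t(O))))
})

test_that("Cramer's V normalization and invariances", {
  expect_equal(cramers_v(100, 100, 2, 2), 1.0)
  expect_equal(cramers_v(0, 50, 3, 4), 0.0)
  expect_equal(cramers_v(20 / 3, 60, 2, 2), sqrt((20 / 3) / 60),
               tolerance = 1e-3)
  expect_lt(abs(cramers_v(20 / 3, 60, 2, 2) - 0.333), 1e-3)
  expect_error(cramers_v(5, 10, 1, 3), "at least 2")
  # scaling counts scales chi2 and n together: V invariant
  set.seed(3)
  O <- matrix(rpois(6, 10) + 1, 2, 3)
  for (m in c(2, 5, 10)) {
    v1 <- cramers_v(as.numeric(chi2_stat(O)), sum(O), 2, 3)
    v2 <- cramers_v(as.numeric(chi2_stat(m * O)), m * sum(O), 2, 3)
    expect_equal(v1, v2, tolerance = 1e-12)
  }
})

test_that("rank_and_select recovers planted informative features", {
  d <- gen_feature_table(n = 1000, p = 50, k_informative = 5,
                         coef_magnitude = 1, noise_sd = 1, seed = 5)
  r <- rank_and_select(d$features, d$activity, k = 5)
  hits <- sum(r$feature[r$selected] %in%
                colnames(d$features)[d$informative])
  expect_gte(hits, 4)
  expect_equal(sum(r$selected), 5L)
  # k = all selects everything
  r_all <- rank_and_select(d$features, d$activity, k = 50)
  expect_true(all(r_all$selected))
  expect_error(rank_and_select(d$features, d$activity, k = 51), "exceeds")
})

test_that("a feature identical to the binned target ranks first with V = 1", {
  set.seed(8)
  y <- rnorm(300)
  bins <- discretize(y, 5)
  X <- cbind(perfect = as.numeric(bins), junk1 = rnorm(300),
             junk2 = rnorm(300))
  r <- rank_and_select(X, y, k = 1, target_bins = 5, feature_bins = 10)
  expect_equal(r$feature[1], "perfect")
  expect_equal(r$cramers_v[1], 1, tolerance = 1e-12)
})

test_that("noise features are selected at close to the uniform rate", {
  # under a null generator, no feature should be selected much more often
  # than k/p over repeated draws
  p <- 20; k <- 4
  counts <- integer(p)
  for (s in 1:40) {
    d <- gen_feature_table(n = 120, p = p, k_informative = 0,
                           coef_magnitude = 0, noise_sd = 1, seed = s)
    r <- rank_and_select(d$features, d$activity, k = k)
    sel <- match(r$feature[r$selected], colnames(d$features))
    counts[sel] <- counts[sel] + 1L
  }
  expect_lt(max(counts) / 40, 3 * k / p)
})
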