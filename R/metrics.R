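# Model evaluation statistics used throughout the workflow.

#' Adjusted coefficient of determination
#'
#' \eqn{R^2_{adj} = 1 - (1 - R^2) (n-1)/(n-p-1)}, where \eqn{R^2} is the
#' squared Pearson correlation between observed and predicted values and
#' \eqn{p} is the number of model parameters charged.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @param p parameter count (for kernel/ensemble learners the package
#'   charges the number of selected features; see the methods vignette).
#' @return Adjusted R-squared.
#' @examples
#' r2_adj(1:10, 1:10 + rnorm(10, 0, 0.1), p = 1)
#' @export
r2_adj <- function(y, yhat, p) {
  n <- length(y)
  .check(n == length(yhat), "r2_adj: length mismatch")
  .check(n > p + 1, "r2_adj: need n > p + 1")
  r2 <- stats::cor(y, yhat)^2
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' External determination coefficient
#'
#' The conventional coefficient of determination on held-out data,
#' \eqn{q^2_{ext} = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2}.
#'
#' @param y observed test values (must not be constant).
#' @param yhat predicted test values.
#' @return q2_ext (<= 1, can be negative).
#' @export
q2_ext <- function(y, yhat) {
  .check(length(y) == length(yhat) && length(y) > 0,
         "q2_ext: length mismatch or empty")
  sst <- sum((y - mean(y))^2)
  .check(sst > 0, "q2_ext: zero-variance observed values (SST = 0)")
  1 - sum((y - yhat)^2) / sst
}

#' Mean absolute error
#' @param y,yhat equal-length numeric vectors.
#' @return MAE.
#' @export
mae <- function(y, yhat) {
  .check(length(y) == length(yhat) && length(y) > 0, "mae: bad input")
  mean(abs(y - yhat))
}

#' Root mean square error
#' @param y,yhat equal-length numeric vectors.
#' @return RMSE (>= MAE).
#' @export
rmse <- function(y, yhat) {
  .check(length(y) == length(yhat) && length(y) > 0, "rmse: bad input")
  sqrt(mean((y - yhat)^2))
}

# Equal-frequency stratified fold assignment on the target.
.stratified_folds <- function(y, folds, seed) {
  n <- length(y)
  bins <- discretize(y, min(10L, max(2L, n %/% folds)))
  with_seed(seed, {
    fold <- integer(n)
    for (b in unique(bins)) {
      idx <- which(bins == b)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    # a final shuffle of fold labels guards against systematic bin-order bias
    fold
  })
}

#' Cross-validated q-squared
#'
#' Tenfold (by default) cross-validation coefficient
#' \eqn{q^2 = (SST - PRESS)/SST}, where PRESS accumulates squared
#' out-of-fold prediction errors over a seeded target-stratified fold
#' partition and SST is taken around the overall mean.
#'
#' @param x feature matrix.
#' @param y response vector.
#' @param spec a \code{\link{learner_spec}}.
#' @param folds number of folds (default 10).
#' @param seed integer seed controlling the fold partition and any
#'   stochastic learner fits.
#' @return List with \code{q2}, \code{press}, \code{sst} and the
#'   out-of-fold \code{predictions}.
#' @export
q2_cv <- function(x, y, spec, folds = 10, seed = 1) {
  x <- as.matrix(x)
  n <- length(y)
  .check(folds >= 2, "q2_cv: folds must be >= 2")
  .check(n >= folds, "q2_cv: fewer observations than folds")
  fold <- .stratified_folds(y, folds, derive_seed(seed, "cv_folds"))
  .check(all(tabulate(fold, folds) >= 1), "q2_cv: empty fold")
  pred <- numeric(n)
  for (f in seq_len(folds)) {
    hold <- fold == f
    reg <- fit_learner(spec, x[!hold, , drop = FALSE], y[!hold],
                       seed = derive_seed(seed, paste0("cv_fit", f)))
    pred[hold] <- predict(reg, x[hold, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  list(q2 = (sst - press) / sst, press = press, sst = sst,
       predictions = pred)
}

#' Paired Wilcoxon signed-rank comparison of absolute errors
#'
#' Two-sided signed-rank test comparing two models' absolute-error vectors
#' on the same molecules. Exact distribution for n <= 25 pairs (after
#' zero-difference removal), normal approximation with continuity
#' correction above.
#'
#' @param abs_err_a,abs_err_b paired absolute errors.
#' @return Two-sided p-value in (0, 1]; 1 (with a warning) when every
#'   difference is zero.
#' @export
wilcoxon_compare <- function(abs_err_a, abs_err_b) {
  .check(length(abs_err_a) == length(abs_err_b),
         "wilcoxon_compare: unpaired input")
  d <- abs_err_a - abs_err_b
  nz <- sum(d != 0)
  if (nz == 0L) {
    warning("wilcoxon_compare: all paired differences are zero; p = 1")
    return(1)
  }
  .check(nz >= 6, "wilcoxon_compare: need >= 6 non-zero differences")
  res <- suppressWarnings(stats::wilcox.test(
    abs_err_a, abs_err_b, paired = TRUE,
    exact = nz <= 25, correct = TRUE))
  unname(res$p.value)
}

#' Full evaluation report for one model
#'
#' Collects the training/test statistics used to compare QSAR models:
#' adjusted R-squared and cross-validated q-squared on the training set,
#' external q-squared, RMSE and MAE on both sets, the overfit flag
#' (R2adj - q2ext > 0.3) and the acceptability flags (q2 >= 0.5 and
#' q2ext >= 0.5).
#'
#' @param y_train,yhat_train training observations and predictions.
#' @param y_test,yhat_test test observations and predictions.
#' @param p parameter count charged in the adjusted R-squared.
#' @param q2 optional cross-validated q2 (from \code{\link{q2_cv}}).
#' @return An object of class \code{"metrics_report"} (named list).
#' @export
metrics_report <- function(y_train, yhat_train, y_test, yhat_test, p,
                           q2 = NA_real_) {
  r2 <- stats::cor(y_train, yhat_train)^2
  radj <- r2_adj(y_train, yhat_train, p)
  q2e <- q2_ext(y_test, yhat_test)
  out <- list(
    n_train = length(y_train), n_test = length(y_test), p = p,
    r2 = r2, r2_adj = radj, q2 = q2, q2_ext = q2e,
    rmse_train = rmse(y_train, yhat_train),
    mae_train = mae(y_train, yhat_train),
    rmse_test = rmse(y_test, yhat_test),
    mae_test = mae(y_test, yhat_test),
    sse = sum((y_train - yhat_train)^2),
    sst = sum((y_train - mean(y_train))^2),
    overfit = isTRUE(radj - q2e > 0.3),
    acceptable_q2 = if (is.na(q2)) NA else q2 >= 0.5,
    acceptable_q2_ext = q2e >= 0.5
  )
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "QSAR metrics (n_train = %d, n_test = %d, p = %d)\n", x$n_train,
    x$n_test, x$p))
  cat(sprintf("  R2 = %.3f  R2adj = %.3f  q2 = %s  q2_ext = %.3f\n",
              x$r2, x$r2_adj,
              if (is.na(x$q2)) "NA" else sprintf("%.3f", x$q2), x$q2_ext))
  cat(sprintf("  train RMSE/MAE = %.3f/%.3f  test RMSE/MAE = %.3f/%.3f\n",
              x$rmse_train, x$mae_train, x$rmse_test, x$mae_test))
  cat(sprintf("  overfit (R2adj - q2_ext > 0.3): %s\n",
              if (x$overfit) "YES" else "no"))
  invisible(x)
}
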