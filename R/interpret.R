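# Model interpretation: one-dimensional sensitivity, fragment alerts,
# stepwise adjusted-R2 deltas, and scaffold analysis of poorly predicted
# molecules.

#' One-dimensional sensitivity importance
#'
#' For each feature, the model response is evaluated on an equally spaced
#' grid of \code{levels} values spanning the feature's observed range while
#' all other features are held at their median; the feature's raw score is
#' the variance of those responses, and scores are normalized to sum to 1
#' across the analyzed features. Constant features score 0.
#'
#' @param model object with a \code{predict(model, newdata)} method fitted
#'   on \code{data}'s feature space (e.g. a \code{"qsar_regressor"} or
#'   \code{"rvm"}).
#' @param data numeric feature matrix (named columns).
#' @param features columns to analyze (default: all).
#' @param levels grid size (>= 3, default 7).
#' @return Named numeric vector of normalized importance scores (sums to 1
#'   unless all raw scores are 0).
#' @export
sensitivity_1d <- function(model, data, features = colnames(data),
                           levels = 7) {
  X <- as.matrix(data)
  .check(levels >= 3, "sensitivity_1d: levels must be >= 3")
  .check(all(features %in% colnames(X)), "sensitivity_1d: unknown feature")
  med <- apply(X, 2L, stats::median)
  raw <- vapply(features, function(nm) {
    rng <- range(X[, nm])
    if (diff(rng) == 0) return(0)
    grid <- matrix(rep(med, each = levels), nrow = levels,
                   dimnames = list(NULL, colnames(X)))
    grid[, nm] <- seq(rng[1L], rng[2L], length.out = levels)
    resp <- predict(model, grid)
    if (is.list(resp)) resp <- resp$fit
    stats::var(as.numeric(resp))
  }, numeric(1))
  tot <- sum(raw)
  if (tot > 0) raw / tot else raw
}

#' Fragment contribution sign from activity counts
#'
#' Counts, among molecules carrying the fragment (bit = 1), how many have
#' activity at or above the alert threshold versus below it. A strict
#' majority above gives a positive contribution, a strict majority below a
#' negative one; ties are flagged undetermined.
#'
#' @param bits binary (0/1) fingerprint column.
#' @param activity aligned activity vector.
#' @param threshold alert threshold on the activity scale (default 3.0,
#'   the usual high-toxicity cut on pLD50).
#' @return List with \code{count_high}, \code{count_low}, \code{sign}
#'   (\code{"positive"}/\code{"negative"}/\code{"undetermined"}),
#'   \code{n_with_fragment}; NULL (with a warning) when no molecule
#'   carries the fragment.
#' @export
fragment_contribution <- function(bits, activity, threshold = 3) {
  .check(all(bits %in% c(0, 1)), "fragment_contribution: bits must be 0/1")
  .check(length(bits) == length(activity),
         "fragment_contribution: length mismatch")
  .check(is.finite(threshold), "fragment_contribution: bad threshold")
  has <- bits == 1
  if (!any(has)) {
    warning("fragment_contribution: fragment present in no molecule")
    return(NULL)
  }
  hi <- sum(activity[has] >= threshold)
  lo <- sum(activity[has] < threshold)
  sign <- if (hi > lo) "positive" else if (lo > hi) "negative"
          else "undetermined"
  list(count_high = hi, count_low = lo, sign = sign,
       n_with_fragment = sum(has), threshold = threshold)
}

#' Adjusted-R2 change when adding a candidate feature to an OLS base model
#'
#' Fits ordinary least squares with and without the candidate column and
#' returns the difference in adjusted R2 (each charged its own parameter
#' count). A rank-deficient augmented fit (candidate collinear with the
#' base) is reported with \code{collinear = TRUE}.
#'
#' @param base_features numeric matrix of base features.
#' @param candidate numeric candidate column.
#' @param activity response vector.
#' @return List with \code{delta} (R2adj gain), \code{r2adj_base},
#'   \code{r2adj_full}, \code{collinear}.
#' @export
stepwise_r2adj_delta <- function(base_features, candidate, activity) {
  X0 <- cbind(1, as.matrix(base_features))
  n <- length(activity)
  p0 <- ncol(X0) - 1L
  .check(n > p0 + 2, "stepwise_r2adj_delta: base model not fittable")
  ols_r2adj <- function(X, p) {
    fit <- stats::lm.fit(X, activity)
    yhat <- activity - fit$residuals
    r2 <- 1 - sum(fit$residuals^2) / sum((activity - mean(activity))^2)
    list(r2adj = 1 - (1 - r2) * (n - 1) / (n - p - 1),
         rank = fit$rank)
  }
  b <- ols_r2adj(X0, p0)
  X1 <- cbind(X0, candidate = as.numeric(candidate))
  f <- ols_r2adj(X1, p0 + 1L)
  list(delta = f$r2adj - b$r2adj,
       r2adj_base = b$r2adj, r2adj_full = f$r2adj,
       collinear = f$rank < ncol(X1))
}

#' Scaffold table of molecules with large prediction errors
#'
#' Selects the molecules whose absolute prediction error exceeds
#' \code{mae_threshold}, extracts their Murcko frameworks, and tabulates
#' framework frequencies (only frameworks shared by at least 2 large-error
#' molecules are reported), together with the number of molecules carrying
#' each framework in the training and test sets and the mean absolute
#' error of the associated large-error molecules. Sorted by frequency
#' descending.
#'
#' @param molecules data.frame with \code{id} and \code{smiles} covering
#'   (at least) all split members.
#' @param split a \code{"dataset_split"}.
#' @param abs_errors named numeric vector of absolute errors (names =
#'   molecule ids, typically the test set).
#' @param mae_threshold error cut (default 1.0).
#' @param min_frequency report only frameworks at or above this frequency
#'   among large-error molecules (default 2).
#' @return data.frame with columns \code{scaffold}, \code{frequency},
#'   \code{n_train}, \code{n_test}, \code{mae}; zero rows when nothing
#'   exceeds the threshold.
#' @export
error_scaffold_table <- function(molecules, split, abs_errors,
                                 mae_threshold = 1, min_frequency = 2) {
  .check(!is.null(names(abs_errors)),
         "error_scaffold_table: abs_errors must be named by molecule id")
  .check(all(names(abs_errors) %in% molecules$id),
         "error_scaffold_table: errors for unknown molecules")
  empty <- data.frame(scaffold = character(0), frequency = integer(0),
                      n_train = integer(0), n_test = integer(0),
                      mae = numeric(0), stringsAsFactors = FALSE)
  big <- abs_errors[abs_errors > mae_threshold]
  if (!length(big)) return(empty)
  frames_all <- murcko_framework(molecules$smiles)
  names(frames_all) <- molecules$id
  big_frames <- frames_all[names(big)]
  keep <- !is.na(big_frames) & nzchar(big_frames)
  big <- big[keep]; big_frames <- big_frames[keep]
  if (!length(big)) return(empty)
  freq <- table(big_frames)
  freq <- freq[freq >= min_frequency]
  if (!length(freq)) return(empty)
  scaf <- names(freq)
  train_frames <- frames_all[split$train_ids]
  test_frames <- frames_all[split$test_ids]
  out <- data.frame(
    scaffold = scaf,
    frequency = as.integer(freq),
    n_train = vapply(scaf, function(s)
      sum(train_frames == s, na.rm = TRUE), integer(1)),
    n_test = vapply(scaf, function(s)
      sum(test_frames == s, na.rm = TRUE), integer(1)),
    mae = vapply(scaf, function(s)
      mean(big[big_frames == s]), numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$scaffold), , drop = FALSE]
  rownames(out) <- NULL
  out
}
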