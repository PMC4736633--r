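# Consensus averaging and the ensemble-variance (STD-DM) applicability
# domain.

#' Consensus prediction by unweighted model averaging
#'
#' Per molecule, the arithmetic mean of the predictions of all models not
#' excluded; every contributing model carries equal weight.
#'
#' @param preds numeric matrix, molecules in rows and models in (named)
#'   columns.
#' @param exclude character vector of model (column) names to drop.
#' @return Numeric vector of consensus predictions, with attribute
#'   \code{models} naming the contributing columns.
#' @examples
#' m <- cbind(a = c(1, 2), b = c(3, 2))
#' consensus_predict(m)
#' @export
consensus_predict <- function(preds, exclude = character(0)) {
  preds <- as.matrix(preds)
  .check(!anyNA(preds), "consensus_predict: missing predictions")
  if (length(exclude)) {
    .check(!is.null(colnames(preds)),
           "consensus_predict: exclusion needs named columns")
    missing_ <- setdiff(exclude, colnames(preds))
    .check(length(missing_) == 0,
           sprintf("consensus_predict: unknown model(s): %s",
                   paste(missing_, collapse = ", ")))
    preds <- preds[, setdiff(colnames(preds), exclude), drop = FALSE]
  }
  .check(ncol(preds) >= 2,
         "consensus_predict: need at least 2 models after exclusion")
  out <- rowMeans(preds)
  attr(out, "models") <- colnames(preds)
  out
}

#' Standard deviation distance to model (STD-DM)
#'
#' Per-molecule sample standard deviation (divisor M - 1 over the M
#' ensemble models) of the model predictions: the ensemble-disagreement
#' distance used to delimit the applicability domain.
#'
#' @param preds numeric matrix, molecules in rows, >= 2 model columns.
#' @return Numeric vector of per-molecule STD-DM values.
#' @export
std_dm <- function(preds) {
  preds <- as.matrix(preds)
  .check(ncol(preds) >= 2, "std_dm: need at least 2 model columns")
  .check(!anyNA(preds), "std_dm: missing predictions")
  apply(preds, 1L, stats::sd)
}

#' Applicability-domain assessment from ensemble disagreement
#'
#' Calibrates a reference disagreement level as the mean STD-DM of the
#' training set; a molecule is inside the applicability domain when its
#' STD-DM does not exceed \code{multiplier} times that reference (default
#' multiplier 3). Coverage is the percentage of test molecules inside.
#'
#' @param train_std training-set STD-DM values (calibration population).
#' @param test_std test-set STD-DM values to assess.
#' @param multiplier margin multiplier (> 0, default 3).
#' @return An object of class \code{"ad_report"}: list with
#'   \code{reference} (mean training STD-DM), \code{multiplier},
#'   \code{threshold}, logical \code{in_domain}, \code{std_dm} (test
#'   values) and \code{coverage} (percent).
#' @export
ad_assess <- function(train_std, test_std, multiplier = 3) {
  .check(length(train_std) > 0, "ad_assess: empty calibration set")
  .check(multiplier > 0, "ad_assess: multiplier must be positive")
  ref <- mean(train_std)
  thr <- multiplier * ref
  inside <- test_std <= thr
  out <- list(reference = ref, multiplier = multiplier, threshold = thr,
              std_dm = test_std, in_domain = inside,
              coverage = 100 * mean(inside))
  class(out) <- "ad_report"
  out
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf(
    "Applicability domain (STD-DM): reference = %.4f, multiplier = %g\n",
    x$reference, x$multiplier))
  cat(sprintf("  threshold = %.4f; coverage = %.1f%% (%d of %d in domain)\n",
              x$threshold, x$coverage, sum(x$in_domain),
              length(x$in_domain)))
  invisible(x)
}
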