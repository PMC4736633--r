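#' Discretize a numeric vector into bins
#'
#' Equal-frequency (quantile) or equal-width binning used to turn
#' continuous features and the continuous activity into the categorical
#' levels a contingency table needs. Vectors with few distinct values
#' (e.g. fingerprint bits) collapse to their native levels; empty bins are
#' merged away.
#'
#' @param values numeric vector.
#' @param n_bins requested number of bins (>= 2).
#' @param strategy \code{"equal_frequency"} (default) or \code{"equal_width"}.
#' @return Integer vector of bin labels in \code{0:(bins-1)}; the realized
#'   number of bins is \code{attr(, "n_bins")}.
#' @examples
#' table(discretize(1:100, 4))
#' @export
discretize <- function(values, n_bins,
                       strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  .check(n_bins >= 2, "discretize: n_bins must be >= 2")
  .check(length(values) >= n_bins, "discretize: fewer values than bins")
  u <- unique(values[!is.na(values)])
  if (length(u) <= 1L) {
    warning("discretize: constant vector, single bin")
    out <- rep(0L, length(values))
    attr(out, "n_bins") <- 1L
    return(out)
  }
  if (length(u) <= n_bins) {
    lab <- match(values, sort(u)) - 1L
    attr(lab, "n_bins") <- length(u)
    return(lab)
  }
  breaks <- if (strategy == "equal_frequency") {
    unique(stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1),
                           type = 1, names = FALSE))
  } else {
    seq(min(values), max(values), length.out = n_bins + 1)
  }
  lab <- cut(values, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  # drop empty bins, relabel contiguously from 0
  lev <- sort(unique(lab))
  out <- match(lab, lev) - 1L
  attr(out, "n_bins") <- length(lev)
  out
}

#' Chi-squared statistic of a contingency table
#'
#' \eqn{\chi^2 = \sum_{ij} (O_{ij} - E_{ij})^2 / E_{ij}} with expected
#' counts \eqn{E_{ij} = (row_i \cdot col_j)/n}. No continuity correction:
#' the statistic is used as a ranking score, not for inference. Expected
#' counts below 5 trigger a diagnostic attribute, not a warning storm.
#'
#' @param table numeric matrix of non-negative observed counts.
#' @return The chi-squared score (>= 0), with attribute
#'   \code{small_expected} = number of cells with \eqn{E_{ij} < 5}.
#' @examples
#' chi2_stat(matrix(c(10, 20, 20, 10), 2))
#' @export
chi2_stat <- function(table) {
  O <- as.matrix(table)
  .check(all(O >= 0), "chi2_stat: negative counts")
  n <- sum(O)
  .check(n > 0, "chi2_stat: empty table")
  rs <- rowSums(O); cs <- colSums(O)
  .check(all(rs > 0) && all(cs > 0),
         "chi2_stat: zero marginal row/column (merge bins first)")
  E <- outer(rs, cs) / n
  stat <- sum((O - E)^2 / E)
  attr(stat, "small_expected") <- sum(E < 5)
  stat
}

#' Cramer's V from a chi-squared score
#'
#' \eqn{V = \sqrt{ (\chi^2/n) / \min(r-1, c-1) }}, the standard
#' normalization mapping association strength to [0, 1].
#'
#' @param chi2 chi-squared score (>= 0).
#' @param n grand total of observations.
#' @param r,c numbers of rows and columns of the contingency table (>= 2).
#' @return V in [0, 1].
#' @examples
#' cramers_v(100, 100, 2, 2)
#' @export
cramers_v <- function(chi2, n, r, c) {
  .check(chi2 >= 0, "cramers_v: chi2 must be >= 0")
  .check(n >= 1, "cramers_v: n must be >= 1")
  .check(r >= 2 && c >= 2, "cramers_v: need at least 2 rows and 2 columns")
  v <- sqrt((chi2 / n) / min(r - 1, c - 1))
  min(v, 1)
}

# Contingency table of two integer label vectors (no empty rows/cols).
.contingency <- function(a, b) {
  tab <- table(a, b)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  unclass(tab)
}

#' Rank features by Cramer's V against a continuous target and select top k
#'
#' The target is binned into \code{target_bins} equal-frequency classes;
#' each continuous feature is binned into \code{feature_bins}
#' equal-frequency bins while binary (fingerprint) columns keep their two
#' native levels. For each feature the chi-squared statistic of the
#' feature-by-target contingency table is transformed to Cramer's V, and
#' the \code{k} features with the highest V are flagged selected. Ties in V
#' break lexicographically on feature name.
#'
#' @param table numeric matrix or data.frame of features (columns named).
#' @param target numeric activity vector.
#' @param k number of features to select.
#' @param target_bins equal-frequency classes for the target (default 5).
#' @param feature_bins equal-frequency bins for continuous features
#'   (default 10).
#' @return A data.frame (one row per feature, sorted by rank) with columns
#'   \code{feature}, \code{chi2}, \code{cramers_v}, \code{rank},
#'   \code{selected}, \code{n_bins_feature}, \code{small_expected}.
#' @export
rank_and_select <- function(table, target, k, target_bins = 5,
                            feature_bins = 10) {
  X <- as.matrix(table)
  .check(!is.null(colnames(X)), "rank_and_select: features must be named")
  .check(k <= ncol(X), "rank_and_select: k exceeds feature count")
  .check(nrow(X) == length(target), "rank_and_select: length mismatch")
  ty <- discretize(target, target_bins)
  res <- lapply(colnames(X), function(nm) {
    fx <- discretize(X[, nm], feature_bins)
    nb <- attr(fx, "n_bins")
    if (nb < 2L) {
      return(data.frame(feature = nm, chi2 = 0, cramers_v = 0,
                        n_bins_feature = nb, small_expected = NA_integer_))
    }
    tab <- .contingency(fx, ty)
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      return(data.frame(feature = nm, chi2 = 0, cramers_v = 0,
                        n_bins_feature = nb, small_expected = NA_integer_))
    }
    x2 <- chi2_stat(tab)
    data.frame(feature = nm, chi2 = as.numeric(x2),
               cramers_v = cramers_v(as.numeric(x2), sum(tab),
                                     nrow(tab), ncol(tab)),
               n_bins_feature = nb,
               small_expected = attr(x2, "small_expected"))
  })
  out <- do.call(rbind, res)
  ord <- order(-out$cramers_v, out$feature, method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$rank <= k
  rownames(out) <- NULL
  out[, c("feature", "chi2", "cramers_v", "rank", "selected",
          "n_bins_feature", "small_expected")]
}
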