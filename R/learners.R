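# Uniform regressor interface over the baseline learners. The registry
# holds the native inverse-distance kNN plus adapters over established
# implementations (randomForest, e1071 SVM, xgboost). Additional learners
# (e.g. local GP or perceptron-ensemble adapters) can be registered by
# supplying fit/predict closures.

.learner_registry <- new.env(parent = emptyenv())

#' Register a learner adapter
#'
#' Extends the learner registry with a custom fit/predict pair, letting
#' external implementations join the consensus without modifying the
#' package.
#'
#' @param name registry key.
#' @param fit function(x, y, hyper, seed) returning an opaque fitted state.
#' @param predict function(state, x) returning numeric predictions.
#' @param defaults named list of default hyperparameters.
#' @return \code{name}, invisibly.
#' @export
register_learner <- function(name, fit, predict, defaults = list()) {
  assign(name, list(fit = fit, predict = predict, defaults = defaults),
         envir = .learner_registry)
  invisible(name)
}

#' List registered learners
#' @return Character vector of registry keys.
#' @export
list_learners <- function() sort(ls(.learner_registry))

#' Learner specification
#'
#' Couples a registry name with hyperparameters, validated against the
#' learner's defaults. Defaults follow published acute-toxicity consensus
#' settings: RF with 230 trees and 105 candidate predictors per node; RBF
#' SVM with kernel width 0.03125, cost 2 and epsilon 0.05; gradient
#' boosting with shrinkage 0.1, depth 7 and 69 rounds; kNN with k in 1-10
#' (default 5); RVM with Laplacian kernel width 0.044.
#'
#' @param name registry key (see \code{\link{list_learners}}).
#' @param ... hyperparameter overrides (must be known keys).
#' @return An object of class \code{"learner_spec"}.
#' @examples
#' learner_spec("rf")
#' learner_spec("knn", k = 3)
#' @export
learner_spec <- function(name, ...) {
  if (!exists(name, envir = .learner_registry, inherits = FALSE)) {
    stop(sprintf("unknown learner '%s'; registry: %s", name,
                 paste(list_learners(), collapse = ", ")), call. = FALSE)
  }
  entry <- get(name, envir = .learner_registry)
  hyper <- entry$defaults
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(hyper))
    .check(length(bad) == 0,
           sprintf("unknown hyperparameter(s) for '%s': %s", name,
                   paste(bad, collapse = ", ")))
    hyper[names(dots)] <- dots
  }
  structure(list(name = name, hyper = hyper), class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  hp <- paste(names(x$hyper), vapply(x$hyper, format, ""), sep = "=",
              collapse = ", ")
  cat(sprintf("<learner_spec> %s (%s)\n", x$name, hp))
  invisible(x)
}

#' Fit a learner
#'
#' Trains the learner named in \code{spec} on a feature matrix and
#' response. Stochastic learners are seeded, so refits with the same seed
#' are bit-identical; the caller's RNG state is untouched.
#'
#' @param spec a \code{\link{learner_spec}}.
#' @param x feature matrix (observations in rows, named columns
#'   recommended).
#' @param y numeric response.
#' @param seed integer seed for stochastic learners.
#' @return An object of class \code{"qsar_regressor"} with the fitted
#'   state, the spec (hyperparameters echoed), feature names and seed.
#' @export
fit_learner <- function(spec, x, y, seed = 1) {
  .check(inherits(spec, "learner_spec"), "fit_learner: need a learner_spec")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  entry <- get(spec$name, envir = .learner_registry)
  state <- with_seed(seed, entry$fit(x, y, spec$hyper, seed))
  structure(list(spec = spec, state = state,
                 feature_names = colnames(x), n_train = nrow(x),
                 seed = seed),
            class = "qsar_regressor")
}

#' @export
print.qsar_regressor <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  fitted on %d observations x %d features (seed %d)\n",
              x$n_train, length(x$feature_names), x$seed))
  invisible(x)
}

#' Predict from a fitted learner
#' @param object a \code{"qsar_regressor"}.
#' @param newdata feature matrix on the training feature space.
#' @param ... unused.
#' @return Numeric prediction vector.
#' @export
predict.qsar_regressor <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (!is.null(object$feature_names) && !is.null(colnames(newdata))) {
    .check(all(object$feature_names %in% colnames(newdata)),
           "predict: newdata lacks training features")
    newdata <- newdata[, object$feature_names, drop = FALSE]
  }
  entry <- get(object$spec$name, envir = .learner_registry)
  as.numeric(entry$predict(object$state, newdata))
}

#' Inverse-distance-weighted k-nearest-neighbour prediction
#'
#' Predicts a query as \eqn{\sum w_i t_i / \sum w_i} with \eqn{w_i = 1/d_i}
#' over the k nearest training points by Euclidean distance. Distance ties
#' at the k-th neighbour include all tied neighbours; zero-distance
#' neighbours short-circuit to the unweighted mean of their targets.
#'
#' @param x training feature matrix.
#' @param y training targets.
#' @param query single query vector or matrix of query rows.
#' @param k number of neighbours (1 <= k <= nrow(x)).
#' @return Numeric prediction(s).
#' @examples
#' knn_predict(matrix(c(0, 1), ncol = 1), c(0, 4), matrix(0.5), k = 2)
#' @export
knn_predict <- function(x, y, query, k) {
  x <- as.matrix(x)
  Q <- if (is.null(dim(query))) matrix(query, nrow = 1L) else as.matrix(query)
  .check(ncol(Q) == ncol(x), "knn_predict: dimension mismatch")
  .check(k >= 1 && k <= nrow(x), "knn_predict: k out of range")
  d2 <- outer(rowSums(Q^2), rowSums(x^2), "+") - 2 * tcrossprod(Q, x)
  d2[d2 < 0] <- 0
  apply(d2, 1L, function(dr) {
    d <- sqrt(dr)
    kd <- sort(d, partial = k)[k]
    sel <- which(d <= kd + 1e-12)      # include distance ties at the k-th
    if (any(d[sel] == 0)) return(mean(y[sel[d[sel] == 0]]))
    w <- 1 / d[sel]
    sum(w * y[sel]) / sum(w)
  })
}

# ---- built-in registry entries -------------------------------------------

register_learner("knn",
  fit = function(x, y, hyper, seed) list(x = x, y = y, k = hyper$k),
  predict = function(state, x) {
    knn_predict(state$x, state$y, x, k = min(state$k, nrow(state$x)))
  },
  defaults = list(k = 5))

register_learner("rf",
  fit = function(x, y, hyper, seed) {
    randomForest::randomForest(
      x = x, y = y,
      ntree = hyper$ntree,
      mtry = min(hyper$mtry, ncol(x)))
  },
  predict = function(state, x) unname(stats::predict(state, x)),
  defaults = list(ntree = 230, mtry = 105))

register_learner("svm",
  fit = function(x, y, hyper, seed) {
    e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
               gamma = hyper$sigma, cost = hyper$C, epsilon = hyper$epsilon,
               scale = FALSE)
  },
  predict = function(state, x) unname(stats::predict(state, x)),
  defaults = list(sigma = 0.03125, C = 2, epsilon = 0.05))

register_learner("gbm",
  fit = function(x, y, hyper, seed) {
    xgboost::xgb.train(
      params = list(eta = hyper$eta, max_depth = hyper$max_depth,
                    objective = "reg:squarederror", nthread = 1),
      data = xgboost::xgb.DMatrix(data = x, label = y),
      nrounds = hyper$nrounds, verbose = 0)
  },
  predict = function(state, x)
    stats::predict(state, xgboost::xgb.DMatrix(data = x)),
  defaults = list(eta = 0.1, max_depth = 7, nrounds = 69))

register_learner("rvm",
  fit = function(x, y, hyper, seed) {
    rvm(x, y,
        kernel = kernel_spec(hyper$kernel, hyper$sigma,
                             hyper$parameterization),
        standardize = hyper$standardize)
  },
  predict = function(state, x) predict(state, x),
  defaults = list(kernel = "laplacian", sigma = 0.044,
                  parameterization = "multiply", standardize = TRUE))
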