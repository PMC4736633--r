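# Seeded synthetic-data generators. Every generator is a pure function of
# its arguments: the same spec always yields the same data, and the caller's
# RNG state is never touched.

#' Sinc benchmark data for sparse kernel regression
#'
#' The classic noisy sinc benchmark: \code{x ~ Uniform(-10, 10)},
#' \code{t = sin(x)/x + e}, \code{e ~ N(0, noise_sd^2)}, with
#' \code{sin(0)/0} defined as 1.
#'
#' @param n number of points (>= 10).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return List with matrix \code{x} (n x 1), targets \code{t}, the
#'   noise-free \code{truth}, and the generating \code{spec}.
#' @examples
#' d <- gen_sinc(100, 0.05, seed = 7)
#' @export
gen_sinc <- function(n, noise_sd = 0.05, seed = 1) {
  .check(n >= 10, "gen_sinc: n must be >= 10")
  with_seed(seed, {
    x <- stats::runif(n, -10, 10)
    truth <- ifelse(x == 0, 1, sin(x) / x)
    t <- truth + stats::rnorm(n, 0, noise_sd)
    list(x = matrix(x, ncol = 1L, dimnames = list(NULL, "x")),
         t = t, truth = truth,
         spec = list(generator = "sinc", n = n, noise_sd = noise_sd,
                     seed = seed))
  })
}

#' Feature table with planted informative features
#'
#' Generates an iid standard-normal feature matrix (optionally with half
#' the columns binarized at zero, mimicking fingerprint bits), and an
#' activity that is a signed linear combination of \code{k_informative}
#' randomly chosen features plus Gaussian noise. Ground truth (which
#' features carry signal, and their coefficients) is returned, so feature
#' selection and metric code can be validated against a known answer.
#'
#' @param n rows (molecules).
#' @param p columns (features).
#' @param k_informative number of signal-carrying features (<= p).
#' @param coef_magnitude absolute effect size of each informative feature.
#' @param noise_sd activity noise standard deviation.
#' @param seed integer seed.
#' @param binarize_half binarize the last \code{floor(p/2)} columns at 0.
#' @return List: \code{features} (n x p matrix, columns \code{f001}...),
#'   \code{activity}, logical \code{informative} mask, \code{coefficients}
#'   (0 for noise features), \code{spec}.
#' @export
gen_feature_table <- function(n, p, k_informative, coef_magnitude = 1,
                              noise_sd = 1, seed = 1, binarize_half = TRUE) {
  .check(k_informative <= p, "gen_feature_table: k_informative > p")
  with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%03d", seq_len(p))))
    if (binarize_half && p >= 2) {
      bin <- seq.int(p - floor(p / 2) + 1L, p)
      X[, bin] <- (X[, bin] > 0) + 0
    }
    idx <- sort(sample.int(p, k_informative))
    signs <- sample(c(-1, 1), k_informative, replace = TRUE)
    beta <- numeric(p)
    beta[idx] <- signs * coef_magnitude
    activity <- drop(X %*% beta) + stats::rnorm(n, 0, noise_sd)
    list(features = X, activity = activity,
         informative = seq_len(p) %in% idx,
         coefficients = beta,
         spec = list(generator = "features", n = n, p = p,
                     k_informative = k_informative,
                     coef_magnitude = coef_magnitude, noise_sd = noise_sd,
                     seed = seed, binarize_half = binarize_half))
  })
}

# Fragment grammar for the toy molecules: substituents in prefix form
# (prepended to the ring SMILES) and suffix form (inside parentheses).
# Phenyl carries its own ring digit (3) and is always placed in the prefix
# slot, so ring numbering never clashes with a core.
.toy_substituents <- data.frame(
  name   = c("cf3", "alkf", "imine", "amine", "methyl", "ethyl", "methoxy",
             "hydroxy", "chloro", "bromo", "nitrile", "phenyl"),
  prefix = c("FC(F)(F)", "FCC", "CN=C", "N", "C", "CC", "CO", "O", "Cl",
             "Br", "N#C", "c3ccccc3"),
  suffix = c("C(F)(F)F", "CCF", "C=NC", "N", "C", "CC", "OC", "O", "Cl",
             "Br", "C#N", "c3ccccc3"),
  stringsAsFactors = FALSE
)

# Each core lists its substitution templates (0..3 attachment points) and
# its ring count.
.toy_cores <- list(
  benzene     = list(tpl = c("c1ccccc1", "%sc1ccccc1", "%sc1ccc(%s)cc1",
                             "%sc1cc(%s)cc(%s)c1"), rings = 1L),
  pyridine    = list(tpl = c("c1ccncc1", "%sc1ccncc1", "%sc1cc(%s)ncc1",
                             "%sc1cc(%s)nc(%s)c1"), rings = 1L),
  pyrimidine  = list(tpl = c("c1cncnc1", "%sc1cncnc1", "%sc1cnc(%s)nc1"),
                     rings = 1L),
  cyclohexane = list(tpl = c("C1CCCCC1", "%sC1CCCCC1", "%sC1CCC(%s)CC1",
                             "%sC1CC(%s)CC(%s)C1"), rings = 1L),
  cyclopentane = list(tpl = c("C1CCCC1", "%sC1CCCC1", "%sC1CC(%s)CC1"),
                      rings = 1L),
  piperidine  = list(tpl = c("C1CCNCC1", "%sC1CCNCC1", "%sC1CCNC(%s)C1"),
                     rings = 1L),
  naphthalene = list(tpl = c("c1ccc2ccccc2c1", "%sc1ccc2ccccc2c1",
                             "%sc1ccc2cc(%s)ccc2c1"), rings = 2L)
)

#' Toy molecule set with planted structure-activity rules
#'
#' Assembles valid SMILES from a fragment grammar (seven mono/bicyclic
#' cores with 0-3 substituents drawn from CF3, alkyl fluoride, imine,
#' amine, alkyl, methoxy, hydroxy, halogens, nitrile and phenyl) and
#' assigns an activity on the pLD50 scale by a known generative rule:
#' \deqn{2.5 + 1.5 [CF3] + 0.6 [alkyl F] - 0.8 [C=N] + 0.3 rings + N(0, 0.3).}
#' The trifluoromethyl boost is the planted positive alert that downstream
#' fragment-analysis code should recover; effect sizes are set so recovery
#' is reliable but not trivial at n = 400 against noise sd 0.3.
#'
#' @param n number of molecules (>= 40).
#' @param seed integer seed.
#' @param noise_sd activity noise (default 0.3).
#' @return A data.frame with columns \code{id}, \code{smiles},
#'   \code{activity}, indicator columns \code{has_cf3}, \code{has_alkf},
#'   \code{has_imine}, \code{rings}, and attribute \code{spec} recording the
#'   generation rule.
#' @export
gen_toy_molecules <- function(n, seed = 1, noise_sd = 0.3) {
  .check(n >= 40, "gen_toy_molecules: n must be >= 40")
  subs <- .toy_substituents
  with_seed(seed, {
    core_i <- sample(length(.toy_cores), n, replace = TRUE)
    nsub <- sample(0:3, n, replace = TRUE, prob = c(0.15, 0.35, 0.3, 0.2))
    smiles <- character(n)
    has <- matrix(FALSE, n, nrow(subs), dimnames = list(NULL, subs$name))
    core_rings <- integer(n)
    for (i in seq_len(n)) {
      core <- .toy_cores[[core_i[i]]]
      core_rings[i] <- core$rings
      k <- min(nsub[i], length(core$tpl) - 1L)
      if (k == 0L) {
        smiles[i] <- core$tpl[1L]
      } else {
        pick <- sample.int(nrow(subs), k, replace = FALSE)
        has[i, pick] <- TRUE
        # phenyl always occupies the prefix slot
        ph <- which(subs$name[pick] == "phenyl")
        if (length(ph)) pick <- c(pick[ph], pick[-ph])
        frags <- c(subs$prefix[pick[1L]],
                   if (k > 1L) subs$suffix[pick[-1L]])
        smiles[i] <- do.call(sprintf, c(list(core$tpl[k + 1L]),
                                        as.list(frags)))
      }
    }
    rings <- core_rings + has[, "phenyl"]
    activity <- 2.5 + 1.5 * has[, "cf3"] + 0.6 * has[, "alkf"] -
      0.8 * has[, "imine"] + 0.3 * rings +
      stats::rnorm(n, 0, noise_sd)
    out <- data.frame(id = sprintf("syn%04d", seq_len(n)),
                      smiles = smiles, activity = as.numeric(activity),
                      has_cf3 = unname(has[, "cf3"]),
                      has_alkf = unname(has[, "alkf"]),
                      has_imine = unname(has[, "imine"]),
                      rings = as.integer(rings),
                      stringsAsFactors = FALSE)
    attr(out, "spec") <- list(generator = "molecules", n = n, seed = seed,
                              noise_sd = noise_sd,
                              rule = "2.5 + 1.5*cf3 + 0.6*alkf - 0.8*imine + 0.3*rings")
    out
  })
}
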