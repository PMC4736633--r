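# Internal helpers: seeded evaluation and per-stage seed derivation.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' All randomness in the workflow flows from one master seed. Each named
#' stage (split, folds, learner fits, ...) gets its own stream through a
#' fixed multiplicative-hash rule, so stages are decoupled: adding a stage
#' never shifts the stream of another.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return An integer in [1, 2^31 - 2], deterministic in (master, stage).
#' @examples
#' derive_seed(42, "split")
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  # Weyl-style mixing in double precision; all intermediates < 2^53.
  h <- (abs(master) %% 2147483647) + 1
  for (ch in utf8ToInt(stage)) {
    h <- (h * 69069 + ch) %% 2147483647
    h <- (h * 3877 + 29573) %% 2147483647
  }
  as.integer(h %% 2147483645L + 1L)
}

# Stop unless all named conditions hold; messages keyed by condition.
.check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
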