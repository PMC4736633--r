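# Independent oracles used across the suite. These deliberately use naive
# loops / enumeration / dense solves so they share no code path with the
# package implementation they check.

# Chi-squared by explicit double loop over cells.
oracle_chi2 <- function(O) {
  n <- sum(O)
  rs <- rowSums(O); cs <- colSums(O)
  acc <- 0
  for (i in seq_len(nrow(O))) {
    for (j in seq_len(ncol(O))) {
      E <- rs[i] * cs[j] / n
      acc <- acc + (O[i, j] - E)^2 / E
    }
  }
  acc
}

# Posterior (Sigma, mu) by a plain dense solve of (beta Phi'Phi + A) m = ...
oracle_posterior <- function(Phi, t, alpha, beta) {
  H <- beta * t(Phi) %*% Phi + diag(alpha, length(alpha))
  Sigma <- solve(H)
  mu <- drop(beta * Sigma %*% t(Phi) %*% t)
  list(Sigma = Sigma, mu = mu)
}

# Exact two-sided Wilcoxon signed-rank p-value by enumeration over all
# 2^n sign assignments of the ranked |d| (assumes no ties, no zeros).
oracle_wilcoxon_exact <- function(d) {
  n <- length(d)
  stopifnot(n <= 14, all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- as.vector(signs %*% r)
  EV <- n * (n + 1) / 4
  p <- mean(abs(V_all - EV) >= abs(V_obs - EV) - 1e-12)
  min(1, p)
}

# Two-pass per-row sample standard deviation.
oracle_row_sd <- function(M) {
  out <- numeric(nrow(M))
  for (i in seq_len(nrow(M))) {
    m <- mean(M[i, ])
    out[i] <- sqrt(sum((M[i, ] - m)^2) / (ncol(M) - 1))
  }
  out
}

# Murcko-style framework membership by iterative terminal-atom pruning on
# an adjacency list (returns the retained atom indices).
oracle_two_core <- function(edges, n) {
  alive <- rep(TRUE, n)
  repeat {
    deg <- rep(0L, n)
    for (e in seq_len(nrow(edges))) {
      if (alive[edges[e, 1]] && alive[edges[e, 2]]) {
        deg[edges[e, 1]] <- deg[edges[e, 1]] + 1L
        deg[edges[e, 2]] <- deg[edges[e, 2]] + 1L
      }
    }
    drop_ <- alive & deg <= 1L
    if (!any(drop_)) break
    alive[drop_] <- FALSE
  }
  which(alive)
}

# Small random prediction matrix fixture.
random_pred_matrix <- function(n, m, seed) {
  set.seed(seed)
  matrix(rnorm(n * m, mean = 3), n, m,
         dimnames = list(NULL, paste0("mod", seq_len(m))))
}
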