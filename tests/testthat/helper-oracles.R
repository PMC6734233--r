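# Independent oracles used across tests; deliberately brute-force and
# separate from the package's implementation paths.

# Classical partial correlation via residuals: correlate the residuals of
# each pair after regressing out all remaining nodes.
oracle_partial_corr <- function(x) {
  k <- ncol(x)
  out <- diag(0, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    others <- x[, -c(i, j), drop = FALSE]
    ri <- if (ncol(others)) stats::residuals(stats::lm(x[, i] ~ others)) else x[, i]
    rj <- if (ncol(others)) stats::residuals(stats::lm(x[, j] ~ others)) else x[, j]
    out[i, j] <- out[j, i] <- stats::cor(ri, rj)
  }
  out
}

# Two-sided Fisher p by explicit enumeration of the hypergeometric support.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided permutation p for the difference of group means, by
# enumerating every assignment of n2 subjects to group 2.
oracle_exact_perm_p <- function(values, n2) {
  n <- length(values)
  obs <- mean(values[(n - n2 + 1):n]) - mean(values[1:(n - n2)])
  combos <- utils::combn(n, n2)
  stats <- apply(combos, 2, function(idx)
    mean(values[idx]) - mean(values[-idx]))
  mean(abs(stats) >= abs(obs) - 1e-12)
}

# Small default spec for fast module tests (defaults overridable).
tiny_spec <- function(...) {
  args <- list(n_em = 6, n_cm = 4, n_nodes = 4, n_volumes = 40, seed = 42)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_spec, args)
}
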