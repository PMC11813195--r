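# Independent oracles used to verify the package's own implementations.
# Each is deliberately brute-force and shares no code with the checked path.

# AUROC by exhaustive pair counting: concordant pairs + half the ties.
oracle_auroc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (same margins) no more probable than
# the observed one.
oracle_fisher_2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) {
    choose(m, x) * choose(n, k - x) / choose(m + n, k)
  }, numeric(1))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided signed-rank p by recursive enumeration over sign vectors
# (independent of the matrix-based enumeration in the package).
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  wdist <- 0
  for (ri in r) wdist <- c(wdist, wdist + ri)  # subset-sum expansion
  mean(abs(wdist - mu) >= abs(w - mu) - 1e-9)
}

# OLS coefficients by explicit normal equations.
oracle_normal_equations <- function(y, X) {
  X1 <- unname(cbind(1, as.matrix(X)))
  unname(drop(solve(t(X1) %*% X1, t(X1) %*% y)))
}

# Small cohort wrapper used across tests: fast defaults, known seed.
tiny_cohort <- function(n = 120, seed = 42, ...) {
  generate_cohort(generator_config(n_physicians = n, seed = seed, ...))
}

fast_pipeline <- function(seed = 1, n_boot = 50L, ...) {
  pipeline_config(seed = seed, n_boot = n_boot, ...)
}
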