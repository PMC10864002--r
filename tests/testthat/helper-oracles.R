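# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# all-pairs AUC by explicit double loop
brute_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# exact one/two-sided Mann-Whitney p by enumeration over rank subsets
# (independent re-derivation; no ties assumed)
brute_mw_p <- function(x, y, alternative) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  u_obs <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2L, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  switch(alternative,
         greater = mean(u_all >= u_obs),
         less = mean(u_all <= u_obs),
         two_sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# true AUC P(X > Y) for X ~ Beta(a1, b1), Y ~ Beta(a2, b2)
beta_true_auc <- function(a1, b1, a2, b2) {
  stats::integrate(function(y) {
    stats::dbeta(y, a2, b2) * (1 - stats::pbeta(y, a1, b1))
  }, 0, 1, rel.tol = 1e-10)$value
}

# seeded evaluation without touching the test RNG stream
with_seed_local <- function(seed, expr) ifnsig:::with_seed(seed, expr)

# small deterministic count matrix for io tests
toy_counts <- function() {
  expression_matrix(
    matrix(c(1, 0, 2,
             3, 4, 0), nrow = 3,
           dimnames = list(c("GA", "GB", "GC"), c("s1", "s2"))),
    layer = "counts")
}
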