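# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# Benjamini-Hochberg by its step-up definition: for the i-th smallest
# p-value, the adjusted value is min over j >= i of m * p_(j) / j, capped
# at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq(i, m), function(j) m * p[o[j]] / j, 1)
    adj[o[i]] <- min(1, cand)
  }
  adj
}

# Two-sided one-sample t p-value by numerical integration of the Student
# density written from its closed form.
t_pvalue_integral <- function(t_stat, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, lower = abs(t_stat), upper = Inf,
                       rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Upper-tail hypergeometric probability P(X >= k) by exhaustive enumeration
# of all C(N, n) draws of n from N with the first K marked.
hyper_pvalue_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Pearson correlation by the direct covariance/variance formula.
pearson_direct <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
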