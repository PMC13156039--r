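# Independent brute-force oracles, deliberately coded differently from the
# package implementations they check.

# Exact two-sided Wilcoxon rank-sum p by bitmask enumeration of all
# assignments of pooled observations to the first sample.
oracle_wilcox_p <- function(x, y) {
  n <- length(x)
  N <- n + length(y)
  r <- rank(c(x, y))
  mu <- n * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n)]) - mu)
  hits <- 0L
  total <- 0L
  for (mask in 0:(2^N - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(N)]
    if (sum(bits) != n) next
    total <- total + 1L
    if (abs(sum(r[bits == 1L]) - mu) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# Benjamini-Hochberg step-up by the textbook formula.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- vapply(seq_len(n), function(i) {
    min(1, min(n * ranked[i:n] / seq(i, n)))
  }, numeric(1))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Exact permutation p for the absolute difference of group means, by full
# enumeration of the group-A index sets.
oracle_perm_p <- function(values, in_a) {
  n_a <- sum(in_a)
  obs <- abs(mean(values[in_a]) - mean(values[!in_a]))
  splits <- utils::combn(length(values), n_a)
  stats <- apply(splits, 2, function(idx) {
    abs(mean(values[idx]) - mean(values[-idx]))
  })
  mean(stats >= obs - 1e-12)
}
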