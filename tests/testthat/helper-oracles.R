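# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive and separate from the implementation paths they check.

# Two-sided Mann-Whitney p by full enumeration of all C(n, n1) label
# assignments: the two-sided tail is twice the smaller one-sided tail of the
# exact (symmetric) U distribution, capped at 1.
mw_perm_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  n <- length(pool)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Hypergeometric upper tail by explicit summation of counting ratios.
hyper_enum_tail <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Hypergeometric upper tail by exhaustive enumeration of every possible draw
# of n items from a universe of N with K marked items (only feasible for
# small N).
hyper_draw_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(apply(draws, 2, function(d) sum(d <= K) >= k))
}

# Monte-Carlo tail of the one-sided KS statistic D+ for samples of n
# uniforms, without sorting: D+ >= d iff the i-th order statistic falls at
# or below i/n - d for some i.
ks_mc_tail <- function(d, n, m = 1e6, seed = 1234) {
  set.seed(seed)
  mat <- matrix(stats::runif(m * n), m, n)
  hit <- rep(FALSE, m)
  for (i in seq_len(n)) {
    cc <- i / n - d
    if (cc < 0) next
    hit <- hit | (rowSums(mat <= cc) >= i)
  }
  mean(hit)
}
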