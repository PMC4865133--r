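# Independent brute-force oracles for the exact tests. These enumerate
# tables / draws directly from binomial coefficients and never call the
# package's code paths (which go through dhyper/phyper).

# Two-sided Fisher p for rbind(c(ma, ua), c(mb, ub)) by full enumeration
# of all tables with the observed margins, summing probabilities no
# larger than the observed one (point-probability rule; the 1e-7
# relative tolerance absorbs floating-point ties).
oracle_fisher2x2 <- function(ma, ua, mb, ub) {
  n1 <- ma + ua
  n2 <- mb + ub
  K <- ma + mb
  N <- n1 + n2
  if (N == 0) return(1)
  xs <- max(0, K - n2):min(K, n1)
  probs <- vapply(xs, function(x) {
    choose(K, x) * choose(N - K, n1 - x) / choose(N, n1)
  }, numeric(1))
  p_obs <- probs[xs == ma]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Upper-tail hypergeometric by direct summation of binomial products.
oracle_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Welch two-sample t-test from the textbook closed form.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# Random 2x2 tables with bounded totals for property tests.
random_tables <- function(n, max_total = 60, seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      ma = sample(0:15, n, TRUE), ua = sample(0:15, n, TRUE),
      mb = sample(0:15, n, TRUE), ub = sample(0:15, n, TRUE))
  })
}
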