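#' Two-sided Fisher exact test for a 2x2 count table
#'
#' Computes the two-sided Fisher exact p-value for the table
#' `rbind(c(m_a, u_a), c(m_b, u_b))` by the point-probability rule: the
#' sum, over all tables with the observed margins, of hypergeometric
#' probabilities no larger than that of the observed table (ties
#' included, with a 1e-7 relative tolerance against floating-point
#' noise). This is the construction used for both the per-window
#' methylation test and the per-feature expression test, so the two
#' share one implementation.
#'
#' All arguments are recycled to a common length and the function is
#' vectorized over tables.
#'
#' @param m_a,u_a Methylated/unmethylated (or count/remainder) reads in
#'   sample A.
#' @param m_b,u_b Same for sample B.
#' @return Numeric vector of p-values in (0, 1]. A table with all four
#'   counts zero is undefined; it returns 1 with a warning.
#' @examples
#' fisher_exact_two_sided(5, 5, 5, 5)     # identical proportions -> 1
#' fisher_exact_two_sided(10, 0, 0, 10)   # 2 / choose(20, 10)
#' @export
fisher_exact_two_sided <- function(m_a, u_a, m_b, u_b) {
  n <- max(length(m_a), length(u_a), length(m_b), length(u_b))
  m_a <- rep_len(m_a, n); u_a <- rep_len(u_a, n)
  m_b <- rep_len(m_b, n); u_b <- rep_len(u_b, n)
  assert_nonneg_int(c(m_a, u_a, m_b, u_b), "Fisher test counts")
  if (any(m_a + u_a + m_b + u_b == 0)) {
    warning("table(s) with all four counts zero: p undefined, returning 1")
  }
  vapply(seq_len(n), function(i) {
    .fisher1(m_a[i], u_a[i], m_b[i], u_b[i])
  }, numeric(1))
}

.fisher1 <- function(ma, ua, mb, ub) {
  N <- ma + ua + mb + ub
  if (N == 0) return(1)
  n1 <- ma + ua            # row margin, sample A
  K <- ma + mb             # column margin, "methylated"
  lo <- max(0, K - (mb + ub))
  hi <- min(K, n1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, K, N - K, n1)
  d_obs <- probs[ma - lo + 1L]
  min(1, sum(probs[probs <= d_obs * (1 + 1e-7)]))
}

#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more marked elements when drawing `n`
#' elements without replacement from a universe of `N` containing `K`
#' marked ones: `sum_{i >= k} C(K, i) C(N - K, n - i) / C(N, n)`.
#' Used for overlap enrichment between DMR sets and between up-regulated
#' target sets. Evaluated in log space via [stats::phyper()], stable for
#' universes up to at least 1e6.
#'
#' The universe size `N` is a required, explicit argument: depending on
#' the comparison it is the number of tested windows or the number of
#' annotated features, and the choice is reported rather than guessed.
#'
#' @param k Observed overlap count.
#' @param K Size of the marked set.
#' @param n Number of draws (size of the second set).
#' @param N Universe size.
#' @return Upper-tail probability; `k = 0` gives exactly 1.
#' @examples
#' hypergeometric_upper_tail(2, 2, 2, 4)  # 1/6
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, len); K <- rep_len(K, len)
  n <- rep_len(n, len); N <- rep_len(N, len)
  assert_nonneg_int(c(k, K, n, N), "hypergeometric arguments")
  if (any(K > N) || any(n > N)) {
    stop_param("inconsistent arguments: need K <= N and n <= N")
  }
  if (any(k > pmin(K, n))) {
    stop_param("inconsistent arguments: need k <= min(K, n)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
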