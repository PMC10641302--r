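# Ewens sampling formula machinery for Fu's FS. The number of distinct
# haplotypes K in a sample of n gene copies under the infinite-alleles
# model with scaled mutation rate theta has
#   P(K = k) = |S(n, k)| theta^k / (theta)_n,
# where |S(n, k)| are unsigned Stirling numbers of the first kind and
# (theta)_n = theta (theta + 1) ... (theta + n - 1). All computations are
# in log space so large n does not overflow.

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log |S(n, k)| for k = 1..n, via the row recurrence
# |S(n+1, k)| = n |S(n, k)| + |S(n, k-1)|.
log_stirling_row <- function(n) {
  row <- 0  # n = 1: |S(1,1)| = 1
  if (n == 1L) return(row)
  for (m in seq_len(n - 1L)) {
    prev <- c(-Inf, row, -Inf)  # pad k = 0 and k = m+1
    nxt <- numeric(m + 1L)
    for (k in seq_len(m + 1L)) {
      lo <- log(m) + prev[k + 1L]  # m * |S(m, k)|
      hi <- prev[k]                # |S(m, k-1)|
      nxt[k] <- if (lo == -Inf) hi else if (hi == -Inf) lo
        else max(lo, hi) + log1p(exp(-abs(lo - hi)))
    }
    row <- nxt
  }
  row
}

#' Distribution of the number of distinct haplotypes under the Ewens
#' sampling formula
#'
#' @param n Sample size (gene copies).
#' @param theta Scaled mutation rate (> 0).
#' @return Numeric vector of length `n`: `P(K = k)` for `k = 1..n`.
#' @examples
#' sum(ewens_haplotype_pmf(10, 2))  # 1
#' @export
ewens_haplotype_pmf <- function(n, theta) {
  if (theta <= 0) stop("theta must be positive")
  ls <- stat_constants(n)$lstirling
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(lp)
}

#' Fu's FS statistic
#'
#' `FS = ln(S' / (1 - S'))` where `S' = P(K >= H_N | theta = theta_pi)`
#' under the Ewens sampling formula: the probability of observing at least
#' as many distinct haplotypes as seen, given the pairwise-difference
#' estimate of theta. Large negative values indicate an excess of
#' haplotypes (growth-like genealogies); large positive values a deficit
#' (decline- or structure-like genealogies).
#'
#' @param summary A [site_summary()] (or any list with fields `n`, `S`,
#'   `H_N`, `theta_pi`).
#' @return The statistic, or `NA` when `S = 0` or the tail probability is
#'   numerically 0 or 1.
#' @export
fu_FS <- function(summary) {
  if (summary$S == 0 || summary$theta_pi <= 0) return(NA_real_)
  fs_from_counts(summary$n, summary$theta_pi, summary$H_N)
}

fs_from_counts <- function(n, theta_pi, H_N) {
  ls <- stat_constants(n)$lstirling
  lp <- ls + seq_len(n) * log(theta_pi) - sum(log(theta_pi + 0:(n - 1)))
  upper <- logsumexp(lp[H_N:n])
  lower <- if (H_N == 1L) -Inf else logsumexp(lp[seq_len(H_N - 1L)])
  if (!is.finite(upper) || !is.finite(lower)) return(NA_real_)
  upper - lower  # log(S'/(1 - S')) with 1 - S' computed as the lower tail
}
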