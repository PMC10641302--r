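# Second moments of the site frequency spectrum under the neutral
# constant-size coalescent (Fu 1995): E[xi_i] = theta / i,
# Var(xi_i) = theta / i + sigma_ii theta^2, Cov(xi_i, xi_j) = sigma_ij
# theta^2. These drive the variance normalization of frequency-spectrum
# test statistics; any linear combination w'xi has
# Var = theta * sum(w_i^2 / i) + theta^2 * w' Sigma w.

harmonic <- function(m) if (m < 1) 0 else sum(1 / seq_len(m))
harmonic2 <- function(m) if (m < 1) 0 else sum(1 / seq_len(m)^2)

#' Covariance coefficients of the site frequency spectrum
#'
#' Returns the matrix of coefficients of `theta^2` in
#' `Cov(xi_i, xi_j)` for a sample of `n` gene copies under the neutral
#' constant-size coalescent, for derived-allele counts `i, j = 1..n-1`.
#'
#' @param n Sample size (gene copies), `n >= 2`.
#' @return An `(n-1) x (n-1)` symmetric matrix.
#' @export
fu_sigma <- function(n) {
  a <- c(0, cumsum(1 / seq_len(n)))  # a[k+1] = sum_{i=1}^{k} 1/i = a_{k+1}
  an <- function(k) a[k]             # a_k = sum_{i=1}^{k-1} 1/i
  beta <- function(i) {
    2 * n * (an(n + 1) - an(i)) / ((n - i + 1) * (n - i)) - 2 / (n - i)
  }
  s <- matrix(0, n - 1, n - 1)
  for (i in seq_len(n - 1)) {
    s[i, i] <- if (2 * i < n) beta(i + 1)
      else if (2 * i == n) 2 * (an(n) - an(i)) / (n - i) - 1 / i^2
      else beta(i) - 1 / i^2
    if (i > 1) for (j in seq_len(i - 1)) {
      s[i, j] <- s[j, i] <-
        if (i + j < n) (beta(i + 1) - beta(i)) / 2
        else if (i + j == n) {
          (an(n) - an(i)) / (n - i) + (an(n) - an(j)) / (n - j) -
            (beta(i) + beta(j + 1)) / 2 - 1 / (i * j)
        } else (beta(j) - beta(j + 1)) / 2 - 1 / (i * j)
    }
  }
  s
}

# Variance coefficients (alpha, beta) of a spectrum statistic
# sum_i w_i xi_i: Var = alpha * theta + beta * theta^2.
spectrum_var_coefs <- function(w, sigma) {
  i <- seq_along(w)
  list(alpha = sum(w^2 / i), beta = drop(w %*% sigma %*% w))
}

# Per-sample-size constants for all statistics, memoised.
.fusim_cache <- new.env(parent = emptyenv())

stat_constants <- function(n) {
  key <- as.character(n)
  if (!is.null(.fusim_cache[[key]])) return(.fusim_cache[[key]])
  stopifnot(n >= 2)
  a1 <- harmonic(n - 1)
  a2 <- harmonic2(n - 1)
  # Tajima (1989)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  # Fu & Li (1993) F*, with the corrected variance constants
  an1 <- a1 + 1 / n
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           2 * (n - 1) * a1 / n^2 - 8 * a2 / n) / (a1^2 + a2)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
           (3 * n * (n - 1))) / a1 - vF
  # Achaz (2008) Y*: contrast of singleton-free pi and singleton-free
  # Watterson estimators, normalized with the exact Fu (1995) covariances
  ystar <- NULL
  if (n >= 4) {
    idx <- 2:(n - 2)
    Npi <- (n - 1) * (n - 2) / 2 - 1
    aprime <- sum(1 / idx)
    w <- numeric(n - 1)
    w[idx] <- idx * (n - idx) / Npi - 1 / aprime
    sigma <- fu_sigma(n)
    vc <- spectrum_var_coefs(w, sigma)
    B <- sum(sigma[idx, idx])
    ystar <- list(Npi = Npi, aprime = aprime, alpha = vc$alpha,
                  beta = vc$beta, theta2_denom = aprime^2 + B)
  }
  out <- list(n = n, a1 = a1, a2 = a2, e1 = e1, e2 = e2, uF = uF, vF = vF,
              ystar = ystar, lstirling = log_stirling_row(n))
  .fusim_cache[[key]] <- out
  out
}
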