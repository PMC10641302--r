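# Independent reference implementations used as oracles. These recompute
# everything from first principles with plain loops and their own copies of
# the published formulas, sharing no code with the package internals.

oracle_site_stats <- function(aln) {
  n <- nrow(aln); L <- ncol(aln)
  S <- 0; Ksum <- 0; etaS <- 0; U <- integer(n); Knos_sum <- 0
  for (j in seq_len(L)) {
    col <- aln[, j]
    tab <- table(col)
    seg <- length(tab) > 1
    if (seg) S <- S + 1
    dd <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      if (col[a] != col[b]) dd <- dd + 1
    Ksum <- Ksum + dd
    sing <- seg && n > 2 && sum(tab == 1) == 1
    if (sing) {
      etaS <- etaS + 1
      carrier <- which(col == names(tab)[tab == 1])
      U[carrier] <- U[carrier] + 1
    } else if (seg) {
      Knos_sum <- Knos_sum + dd
    }
  }
  npairs <- n * (n - 1) / 2
  haps <- apply(aln, 1, paste, collapse = "")
  list(n = n, S = S, K = Ksum / npairs, eta_S = etaS,
       H_N = length(unique(haps)), U = U, K_nosing = Knos_sum / npairs)
}

oracle_tajima_D <- function(aln) {
  st <- oracle_site_stats(aln)
  n <- st$n; S <- st$S
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (st$K - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

oracle_fu_li_Fstar <- function(aln) {
  st <- oracle_site_stats(aln)
  n <- st$n; S <- st$S
  if (S == 0) return(NA_real_)
  a <- sum(1 / (1:(n - 1))); b <- sum(1 / (1:(n - 1))^2)
  an1 <- a + 1 / n
  v <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
          2 * (n - 1) * a / n^2 - 8 * b / n) / (a^2 + b)
  u <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) / (3 * n * (n - 1))) / a - v
  (st$K - (n - 1) / n * st$eta_S) / sqrt(u * S + v * S^2)
}

oracle_R2 <- function(aln) {
  st <- oracle_site_stats(aln)
  if (st$S == 0) return(NA_real_)
  sqrt(sum((st$U - st$K / 2)^2) / st$n) / st$S
}

oracle_ZnS <- function(aln) {
  n <- nrow(aln)
  bi <- which(apply(aln, 2, function(col) length(unique(col)) == 2))
  if (length(bi) < 2) return(NA_real_)
  r2 <- c()
  for (a in 1:(length(bi) - 1)) for (b in (a + 1):length(bi)) {
    x <- aln[, bi[a]]; y <- aln[, bi[b]]
    pA <- mean(x == x[1]); pB <- mean(y == y[1])
    pAB <- mean(x == x[1] & y == y[1])
    D <- pAB - pA * pB
    r2 <- c(r2, D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  }
  mean(r2)
}

oracle_Hd <- function(aln) {
  n <- nrow(aln)
  p <- table(apply(aln, 1, paste, collapse = "")) / n
  n / (n - 1) * (1 - sum(p^2))
}

# Brute-force Ewens sampling formula over integer partitions of n.
oracle_partitions <- function(n, max = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (k in min(n, max):1)
    for (p in oracle_partitions(n - k, k)) out[[length(out) + 1]] <- c(k, p)
  out
}

oracle_esf_prob <- function(part, theta) {
  n <- sum(part)
  a <- table(part)
  j <- as.integer(names(a))
  exp(lfactorial(n) - sum(log(theta + 0:(n - 1))) +
        sum(a * (log(theta) - log(j)) - lfactorial(a)))
}

oracle_ewens_tail <- function(n, theta, H) {
  pp <- oracle_partitions(n)
  sum(vapply(pp, function(p) if (length(p) >= H) oracle_esf_prob(p, theta) else 0, 0))
}

# Linear-interpolation percentile computed directly from order statistics.
oracle_percentile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Unique proportion by interval measure: the part of [FL, FU] not covered
# by [NL, NU], as a fraction of the fusion interval's width.
oracle_unique_prop <- function(f, nf) {
  width <- f$upper - f$lower
  overlap <- max(0, min(f$upper, nf$upper) - max(f$lower, nf$lower))
  (width - overlap) / width
}

random_alignment <- function(n, L, p_mut = 0.2) {
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  aln <- matrix(rep(anc, each = n), n, L)
  nmut <- stats::rbinom(1, n * L, p_mut / n)
  for (m in seq_len(nmut)) {
    i <- sample.int(n, 1); j <- sample.int(L, 1)
    aln[i, j] <- sample(setdiff(c("A", "C", "G", "T"), aln[i, j]), 1)
  }
  aln
}

canonical_DL <- function() canonical_fusion_scenarios()
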