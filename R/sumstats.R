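#' Per-locus site frequency summary
#'
#' Counts the quantities that feed every neutrality statistic: segregating
#' sites `S` (each polymorphic column counts once, multi-allelic or not),
#' mean pairwise differences `K` (`theta_pi`; any state mismatch counts),
#' singleton sites `eta_S` (columns where exactly one sequence carries a
#' minority state present once), observed haplotype count `H_N`,
#' Watterson's `theta_W = S / a_n`, plus the singleton-free pairwise
#' differences and per-sequence singleton loads used by Y* and R2.
#'
#' @param alignment A matrix with one row per sequence: characters over
#'   `A C G T` (a locus alignment) or integers (e.g. 0/1 segregating-site
#'   patterns).
#' @return An object of class `site_summary`.
#' @examples
#' aln <- rbind(c("A","A","A","A"), c("A","A","A","A"),
#'              c("T","T","T","A"), c("T","T","T","A"))
#' site_summary(aln)$K  # 2.0
#' @export
site_summary <- function(alignment) {
  if (!is.matrix(alignment)) stop("alignment must be a matrix")
  n <- nrow(alignment)
  L <- ncol(alignment)
  if (n < 2) stop("need at least 2 sequences")
  states <- unique(as.vector(alignment))
  if (anyNA(states)) stop("alignment contains missing values")
  cnt <- matrix(0L, length(states), L)
  for (s in seq_along(states))
    cnt[s, ] <- .colSums(alignment == states[s], n, L)
  npairs <- n * (n - 1) / 2
  same_pairs <- .colSums(cnt * (cnt - 1L) / 2, nrow(cnt), L)
  seg <- which(apply(cnt > 0L, 2L, sum) > 1L)
  S <- length(seg)
  diff_pairs <- npairs - same_pairs
  K <- sum(diff_pairs[seg]) / npairs
  # singleton columns: exactly one sequence carries a count-1 minority
  # state (for n = 2 both states are carried once, so nothing is a minority)
  n_sing_state <- .colSums(cnt == 1L, nrow(cnt), L)
  sing_cols <- if (n == 2L) integer(0) else intersect(seg, which(n_sing_state == 1L))
  U <- integer(n)
  for (j in sing_cols) {
    s <- which(cnt[, j] == 1L)
    U[which(alignment[, j] == states[s])] <- U[which(alignment[, j] == states[s])] + 1L
  }
  eta_S <- length(sing_cols)
  K_nosing <- sum(diff_pairs[setdiff(seg, sing_cols)]) / npairs
  hap <- apply(alignment, 1L, paste, collapse = "")
  H_N <- length(unique(hap))
  cst <- stat_constants(n)
  structure(list(n = n, L = L, S = S, K = K, eta_S = eta_S, H_N = H_N,
                 theta_pi = K, theta_w = S / cst$a1,
                 a_n = cst$a1, b_n = cst$a2,
                 K_nosing = K_nosing, U = U),
            class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf("site summary: n = %d, S = %d, K = %.3f, eta_S = %d, H_N = %d, theta_W = %.3f\n",
              x$n, x$S, x$K, x$eta_S, x$H_N, x$theta_w))
  invisible(x)
}

#' Tajima's D
#'
#' The normalized contrast of the pairwise-difference estimator of theta
#' (`K`) against Watterson's `S / a_n`. Negative values indicate an excess
#' of rare variants (growth-like); positive values an excess of
#' intermediate-frequency variants (decline- or structure-like).
#'
#' @param summary A [site_summary()].
#' @return The statistic, or `NA` when `S = 0`.
#' @export
tajima_D <- function(summary) {
  s <- summary
  if (s$S == 0) return(NA_real_)
  cst <- stat_constants(s$n)
  (s$K - s$S / cst$a1) / sqrt(cst$e1 * s$S + cst$e2 * s$S * (s$S - 1))
}

#' Fu and Li's F* (no outgroup)
#'
#' Contrasts the pairwise-difference estimator against the singleton-based
#' estimator `((n - 1) / n) * eta_S`, normalized with the corrected
#' variance constants.
#'
#' @param summary A [site_summary()].
#' @return The statistic, or `NA` when `S = 0`.
#' @export
fu_li_F_star <- function(summary) {
  s <- summary
  if (s$S == 0) return(NA_real_)
  cst <- stat_constants(s$n)
  (s$K - (s$n - 1) / s$n * s$eta_S) /
    sqrt(cst$uF * s$S + cst$vF * s$S^2)
}

#' Ramos-Onsins and Rozas's R2
#'
#' `R2 = sqrt(mean((U_i - K/2)^2)) / S`, where `U_i` is the number of
#' singleton sites carried by sequence `i`. Small values indicate the
#' star-like genealogies of population growth.
#'
#' @param summary A [site_summary()].
#' @param alignment Optional alignment; only needed if `summary` lacks the
#'   per-sequence singleton counts `U`.
#' @return The statistic, or `NA` when `S = 0`.
#' @export
ramos_onsins_R2 <- function(summary, alignment = NULL) {
  s <- summary
  if (is.null(s$U)) {
    if (is.null(alignment)) stop("need per-sequence singleton counts or an alignment")
    s <- site_summary(alignment)
  }
  if (s$S == 0) return(NA_real_)
  sqrt(mean((s$U - s$K / 2)^2)) / s$S
}

#' Achaz's Y* (singleton-free neutrality test)
#'
#' Contrasts the pairwise-difference and Watterson estimators recomputed
#' after discarding singleton sites, so the statistic is robust to
#' sequencing error concentrated in singletons. The variance normalization
#' uses the exact covariances of the site frequency spectrum.
#'
#' @param summary A [site_summary()].
#' @return The statistic, or `NA` when `S - eta_S <= 0` or `n < 4`.
#' @export
achaz_Y_star <- function(summary) {
  s <- summary
  Sp <- s$S - s$eta_S
  if (Sp <= 0 || s$n < 4) return(NA_real_)
  y <- stat_constants(s$n)$ystar
  npairs <- s$n * (s$n - 1) / 2
  pi_star <- s$K_nosing * npairs / y$Npi
  thW <- Sp / y$aprime
  th2 <- max(Sp * (Sp - 1), 0) / y$theta2_denom
  v <- y$alpha * thW + y$beta * th2
  if (v <= 0) return(NA_real_)
  (pi_star - thW) / sqrt(v)
}

#' Kelly's ZnS
#'
#' Mean of the squared allele-frequency correlation `r^2` over all pairs of
#' biallelic segregating sites. High values mean strong linkage
#' disequilibrium: few, deeply differentiated haplotypes.
#'
#' @param alignment A matrix with one row per sequence.
#' @return The statistic, or `NA` with fewer than two biallelic
#'   segregating sites. Sites with more than two states are excluded from
#'   the pairing.
#' @export
kelly_ZnS <- function(alignment) {
  n <- nrow(alignment)
  states_per_col <- apply(alignment, 2L, function(col) length(unique(col)))
  bi <- which(states_per_col == 2L)
  if (length(bi) < 2L) return(NA_real_)
  X <- vapply(bi, function(j) as.numeric(alignment[, j] == alignment[1L, j]),
              numeric(n))
  r2 <- stats::cor(X)^2
  mean(r2[upper.tri(r2)])
}

#' Nei's haplotype diversity
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))`: the probability that two randomly
#' drawn haplotypes differ, with the small-sample correction.
#'
#' @param alignment A matrix with one row per sequence.
#' @return Haplotype diversity in `[0, 1]`.
#' @export
nei_Hd <- function(alignment) {
  n <- nrow(alignment)
  hap <- apply(alignment, 1L, paste, collapse = "")
  p <- table(hap) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Multi-locus summary statistic profile
#'
#' Computes all six neutrality statistics plus haplotype diversity for each
#' locus, and their across-locus means over the loci where each statistic
#' is defined (statistics undefined at `S = 0`, or with fewer than two
#' biallelic sites for ZnS, are excluded from the mean and counted in
#' `n_defined`).
#'
#' @param dataset A `haplotype_dataset` (from [simulate_pod()]), a
#'   `segregating_patterns` (from [simulate_null_replicate()]), or a plain
#'   list of alignment matrices.
#' @return An object of class `sumstat_profile` with components
#'   `per_locus` (data frame), `across_loci` (named means), `n_defined`,
#'   and `Hd_var` (sampling variance of Hd across loci).
#' @export
sumstat_profile <- function(dataset) {
  loci <- if (inherits(dataset, "haplotype_dataset")) dataset$loci else dataset
  if (!length(loci)) stop("need at least one locus")
  per <- t(vapply(loci, locus_statistics, numeric(11L)))
  per_locus <- data.frame(locus = seq_along(loci), per)
  stats <- c("D", "Fstar", "FS", "R2", "Ystar", "ZnS")
  across <- colMeans(per_locus[c(stats, "Hd")], na.rm = TRUE)
  structure(list(
    per_locus = per_locus,
    across_loci = across,
    n_defined = colSums(!is.na(per_locus[stats])),
    Hd_var = if (nrow(per_locus) > 1) stats::var(per_locus$Hd) else NA_real_),
    class = "sumstat_profile")
}

locus_statistics <- function(aln) {
  sm <- site_summary(aln)
  c(S = sm$S, K = sm$K, eta_S = sm$eta_S, theta_w = sm$theta_w,
    D = tajima_D(sm), Fstar = fu_li_F_star(sm), FS = fu_FS(sm),
    R2 = ramos_onsins_R2(sm), Ystar = achaz_Y_star(sm),
    ZnS = kelly_ZnS(aln), Hd = nei_Hd(aln))
}

#' @export
print.sumstat_profile <- function(x, ...) {
  cat(sprintf("Summary statistic profile over %d loci\n", nrow(x$per_locus)))
  cat("Across-locus means (defined loci only):\n")
  print(round(x$across_loci, 4))
  cat(sprintf("Mean Hd = %.3f (across-locus variance %.4f)\n",
              x$across_loci[["Hd"]], x$Hd_var))
  invisible(x)
}

# Vectorized statistics from per-locus count summaries (columns S, K,
# etaS, Knos, Hn, R2, ZnS), as produced by the compiled null-replicate
# simulator. Returns a matrix with columns D, Fstar, FS, R2, Ystar, ZnS.
stats_from_counts <- function(n, M) {
  cst <- stat_constants(n)
  S <- M[, "S"]; K <- M[, "K"]; etaS <- M[, "etaS"]
  def <- S > 0
  D <- ifelse(def, (K - S / cst$a1) /
                sqrt(cst$e1 * S + cst$e2 * S * (S - 1)), NA_real_)
  Fst <- ifelse(def, (K - (n - 1) / n * etaS) /
                  sqrt(cst$uF * S + cst$vF * S^2), NA_real_)
  Sp <- S - etaS
  Y <- rep(NA_real_, length(S))
  if (!is.null(cst$ystar)) {
    y <- cst$ystar
    npairs <- n * (n - 1) / 2
    ok <- Sp > 0
    thW <- Sp / y$aprime
    v <- y$alpha * thW + y$beta * pmax(Sp * (Sp - 1), 0) / y$theta2_denom
    ok <- ok & v > 0
    Y[ok] <- (M[ok, "Knos"] * npairs / y$Npi - thW[ok]) / sqrt(v[ok])
  }
  FS <- fs_vectorized(n, K, M[, "Hn"], def)
  cbind(D = D, Fstar = Fst, FS = FS, R2 = M[, "R2"], Ystar = Y,
        ZnS = M[, "ZnS"])
}

fs_vectorized <- function(n, theta, Hn, def) {
  out <- rep(NA_real_, length(theta))
  idx <- which(def & theta > 0)
  if (!length(idx)) return(out)
  ls <- stat_constants(n)$lstirling
  k <- seq_len(n)
  for (i in idx) {
    lp <- ls + k * log(theta[i]) - sum(log(theta[i] + 0:(n - 1)))
    h <- Hn[i]
    upper <- logsumexp(lp[h:n])
    lower <- if (h == 1) -Inf else logsumexp(lp[seq_len(h - 1)])
    out[i] <- if (is.finite(upper) && is.finite(lower)) upper - lower else NA_real_
  }
  out
}
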