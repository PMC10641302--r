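#' Finite-site mutation model (HKY + invariant sites + discrete gamma)
#'
#' The canonical model of the study: HKY substitution with equal base
#' frequencies, a transition/transversion ratio of 2, 10% invariant sites,
#' two discrete gamma rate categories, and a mutation rate of 1e-7
#' substitutions per site per generation. With equal base frequencies a
#' ts/tv *ratio* R corresponds to the HKY rate parameter `kappa = 2 R`
#' (in general `kappa = R (pA + pG)(pC + pT) / (pA pG + pC pT)`).
#' Rate categories follow the discrete-gamma mean method, so the mean rate
#' over *variable* sites is 1; invariant sites never mutate, making the
#' genome-wide mean rate `(1 - prop_invariant) * mu`.
#'
#' @param mu Substitutions per site per generation.
#' @param tstv_ratio Transition/transversion ratio (flux ratio, not kappa).
#' @param base_freqs Equilibrium frequencies of A, C, G, T (must sum to 1).
#' @param prop_invariant Fraction of sites that cannot mutate, in `[0, 1)`.
#' @param gamma_categories Number of discrete gamma rate classes (>= 1).
#' @param gamma_shape Shape of the gamma rate distribution. The study
#'   source does not pin this value; 1.0 is the package default.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(mu = 1e-7, tstv_ratio = 2,
                           base_freqs = rep(0.25, 4), prop_invariant = 0.10,
                           gamma_categories = 2, gamma_shape = 1.0) {
  if (mu < 0) stop("mu must be non-negative")
  if (abs(sum(base_freqs) - 1) > 1e-8 || length(base_freqs) != 4L ||
      any(base_freqs <= 0))
    stop("base_freqs must be four positive frequencies summing to 1")
  if (prop_invariant < 0 || prop_invariant >= 1)
    stop("prop_invariant must lie in [0, 1)")
  if (gamma_categories < 1) stop("gamma_categories must be >= 1")
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  structure(list(mu = mu, tstv_ratio = tstv_ratio, base_freqs = base_freqs,
                 prop_invariant = prop_invariant,
                 gamma_categories = as.integer(gamma_categories),
                 gamma_shape = gamma_shape),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf(
    "HKY mutation model: mu = %g, ts/tv = %g, %g%% invariant, %d gamma categories (shape %g)\n",
    x$mu, x$tstv_ratio, 100 * x$prop_invariant, x$gamma_categories,
    x$gamma_shape))
  invisible(x)
}

#' Discrete gamma rate categories (mean method)
#'
#' Cuts a Gamma(shape, rate = shape) distribution (mean 1) into `k`
#' equal-probability bins and returns the conditional mean rate of each
#' bin, so the category rates average exactly 1.
#'
#' @param shape Gamma shape parameter.
#' @param k Number of categories.
#' @return Numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k) {
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1L) / k, shape = shape, rate = shape)
  p_up <- c(stats::pgamma(q, shape = shape + 1, rate = shape), 1)
  k * diff(c(0, p_up))
}

# HKY rate matrix scaled to one expected substitution per unit branch
# length, with its eigendecomposition precomputed for fast P(t).
hky_machinery <- function(mm) {
  p <- mm$base_freqs
  R <- mm$tstv_ratio
  kappa <- R * (p[1] + p[3]) * (p[2] + p[4]) / (p[1] * p[3] + p[2] * p[4])
  is_ts <- matrix(FALSE, 4, 4)
  is_ts[1, 3] <- is_ts[3, 1] <- is_ts[2, 4] <- is_ts[4, 2] <- TRUE
  Q <- matrix(rep(p, each = 4), 4, 4)
  Q[is_ts] <- Q[is_ts] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-p * diag(Q))  # mean rate 1
  e <- eigen(Q)
  list(values = Re(e$values), vectors = Re(e$vectors),
       inv = solve(Re(e$vectors)))
}

hky_P <- function(mach, d) {
  P <- mach$vectors %*% (exp(mach$values * d) * mach$inv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Drop HKY mutations onto a genealogy
#'
#' Produces one locus alignment. Each site is independently invariant
#' (probability `prop_invariant`) or assigned one of the discrete gamma
#' rate classes; the ancestral sequence is drawn from the equilibrium base
#' frequencies; substitutions then occur along each branch following the
#' HKY process at rate `mu * relative_rate` per site per generation.
#'
#' @param genealogy A [simulate_genealogy()] result.
#' @param mm A [mutation_model()].
#' @param locus_length Alignment length in base pairs (>= 1).
#' @param seed Optional integer seed.
#' @return A character matrix (`n_alleles` rows over `A C G T`), rows named
#'   `sample{i}_allele{j}` (two alleles per diploid individual).
#' @export
apply_mutations <- function(genealogy, mm, locus_length, seed = NULL) {
  if (locus_length < 1) stop("locus_length must be >= 1")
  n <- genealogy$n
  with_seed(seed, {
    rates <- c(0, discrete_gamma_rates(mm$gamma_shape, mm$gamma_categories))
    probs <- c(mm$prop_invariant,
               rep((1 - mm$prop_invariant) / mm$gamma_categories,
                   mm$gamma_categories))
    site_class <- sample.int(length(rates), locus_length, replace = TRUE,
                             prob = probs)
    mach <- hky_machinery(mm)
    root <- 2L * n - 1L
    seqs <- vector("list", root)
    seqs[[root]] <- sample.int(4L, locus_length, replace = TRUE,
                               prob = mm$base_freqs)
    # visit children after parents: internal nodes are in increasing time
    # order, so descending node id works
    for (node in seq.int(root - 1L, 1L)) {
      par <- genealogy$parent[node]
      len <- genealogy$time[par] - genealogy$time[node]
      child <- seqs[[par]]
      for (cl in seq_along(rates)) {
        idx <- which(site_class == cl)
        if (!length(idx) || rates[cl] == 0) next
        d <- mm$mu * rates[cl] * len
        if (d == 0) next
        P <- hky_P(mach, d)
        sub <- child[idx]
        u <- stats::runif(length(idx))
        for (b in 1:4) {
          at <- which(sub == b)
          if (length(at))
            sub[at] <- findInterval(u[at], cumsum(P[b, 1:3])) + 1L
        }
        child[idx] <- sub
      }
      seqs[[node]] <- child
    }
    aln <- matrix("", n, locus_length)
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n)) aln[i, ] <- bases[seqs[[i]]]
    rownames(aln) <- sprintf("sample%d_allele%d",
                             (seq_len(n) + 1L) %/% 2L, (seq_len(n) - 1L) %% 2L + 1L)
    aln
  })
}

#' Simulate a pseudo-observed dataset (POD)
#'
#' Simulates `comp$n_loci` independent loci under a demographic model: one
#' coalescent genealogy per locus (free recombination between loci, none
#' within), with finite-site HKY mutation. This is the synthetic-data
#' generator for the whole study pipeline.
#'
#' @param model A demographic model (canonically a fusion scenario; any
#'   [single_deme_model()] is also accepted, e.g. for calibration runs).
#' @param comp A [dataset_composition()].
#' @param mm A [mutation_model()]; defaults to the canonical model.
#' @param seed Optional integer seed; per-locus streams are derived from it
#'   deterministically.
#' @return An object of class `haplotype_dataset`: list of locus alignments
#'   plus provenance (`model`, `comp`, `seed`).
#' @examples
#' pod <- simulate_pod(canonical_fusion_scenarios()$DL9,
#'                     dataset_composition(10, 200, 2), seed = 1)
#' @export
simulate_pod <- function(model, comp, mm = mutation_model(), seed = NULL) {
  validate_model(model)
  loci <- vector("list", comp$n_loci)
  for (l in seq_len(comp$n_loci)) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, l)
    g <- simulate_genealogy(model, comp$n_alleles, seed = s)
    loci[[l]] <- apply_mutations(g, mm, comp$locus_length,
                                 seed = if (is.null(s)) NULL else s + 1L)
  }
  structure(list(loci = loci, model = model, comp = comp, mm = mm,
                 seed = seed),
            class = "haplotype_dataset")
}

#' @export
print.haplotype_dataset <- function(x, ...) {
  cat(sprintf("Haplotype dataset: %d loci x %d alleles x %d bp\n",
              x$comp$n_loci, x$comp$n_alleles, x$comp$locus_length))
  invisible(x)
}

# Convert a demographic model to coalescent-scaled epochs: time in units
# of 2 * base_Ne generations, sizes relative to base_Ne.
coal_epochs <- function(model) {
  if (inherits(model, "fusion_scenario")) {
    list(fusion = TRUE,
         t_fuse = model$t_fuse / (2 * model$base_Ne),
         t_div = model$t_div / (2 * model$base_Ne),
         mix = model$mix, breaks = 0, sizes = 1)
  } else {
    ep <- size_epochs(model)
    list(fusion = FALSE, breaks = ep$breaks / (2 * model$base_Ne),
         sizes = ep$sizes / model$base_Ne)
  }
}

#' Simulate an infinite-sites null replicate seeded by Watterson's theta
#'
#' The distribution-estimation path of the study: one coalescent genealogy
#' per locus under the demographic model, with time rescaled to units of
#' `2 * base_Ne` generations, and mutations dropped under the
#' infinite-sites model at rate `theta / 2` per lineage per time unit (so
#' the expected pairwise difference equals `theta` under constant size).
#' Event times of the model (fusion, bottleneck, ...) are converted to
#' coalescent units via the model's own `base_Ne`; `theta` scales only the
#' mutation process.
#'
#' @param model A demographic model.
#' @param n_alleles Sampled gene copies per locus.
#' @param theta_per_locus Non-negative Watterson theta, one value per locus.
#' @param seed Optional integer seed.
#' @return A list of 0/1 haplotype matrices (`n_alleles` rows, one column
#'   per segregating site; 1 = derived state), class
#'   `segregating_patterns`.
#' @examples
#' pats <- simulate_null_replicate(single_deme_model("constant", 10000),
#'                                 10, c(5, 5), seed = 1)
#' @export
simulate_null_replicate <- function(model, n_alleles, theta_per_locus,
                                    seed = NULL) {
  validate_model(model)
  if (any(theta_per_locus < 0)) stop("theta must be non-negative")
  n <- n_alleles
  loci <- vector("list", length(theta_per_locus))
  for (l in seq_along(theta_per_locus)) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, l)
    loci[[l]] <- with_seed(s, {
      g <- simulate_genealogy(model, n, seed = NULL)
      # branch lengths are in generations; one coalescent time unit is
      # 2 * base_Ne generations, over which mutations arrive at theta / 2
      drop_infinite_sites(g, theta_per_locus[l], scale = 2 * model$base_Ne)
    })
  }
  structure(loci, class = "segregating_patterns")
}

drop_infinite_sites <- function(g, theta, scale = 1) {
  n <- g$n
  notroot <- seq_len(2L * n - 2L)
  len <- g$time[g$parent[notroot]] - g$time[notroot]
  nmut <- stats::rpois(1L, theta / 2 * sum(len) / scale)
  if (nmut == 0L) return(matrix(0L, n, 0L))
  edge <- sample.int(length(len), nmut, replace = TRUE, prob = len)
  below <- descendant_leaves(g)
  mat <- matrix(0L, n, nmut)
  for (j in seq_len(nmut)) mat[below[[edge[j]]], j] <- 1L
  rownames(mat) <- paste0("hap", seq_len(n))
  mat
}

# List of leaf index vectors below each node.
descendant_leaves <- function(g) {
  n <- g$n
  below <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) below[[i]] <- i
  kids <- split(seq_len(2L * n - 2L), g$parent[seq_len(2L * n - 2L)])
  for (node in seq.int(n + 1L, 2L * n - 1L))
    below[[node]] <- c(below[[kids[[as.character(node)]][1]]],
                       below[[kids[[as.character(node)]][2]]])
  below
}
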