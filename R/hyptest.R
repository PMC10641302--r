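#' Test a POD against the constant-size null
#'
#' The traditional hypothesis-testing framework: the observed across-locus
#' mean of each statistic is compared with its null distribution under a
#' constant-size history, estimated from `n_reps` coalescent replicates
#' seeded with the POD's per-locus Watterson theta. Empirical tail
#' probabilities use the `(r + 1) / (N + 1)` estimator. By default the
#' test is two-sided with `alpha / 2` in each tail (`alpha = 0.05`, but
#' 0.02 for FS); a one-tailed variant is available for sensitivity
#' analysis. Significantly negative `D`, `F*`, `FS`, `Y*` or significantly
#' small `R2`, `ZnS` are read as population growth; significantly positive
#' or large values as decline; anything else as constancy.
#'
#' @param pod A `haplotype_dataset` with at least one polymorphic locus.
#' @param n_reps Null replicates (canonically 1000).
#' @param seed Optional integer seed.
#' @param alpha Significance level for `D`, `F*`, `R2`, `Y*`, `ZnS`.
#' @param alpha_FS Significance level for Fu's FS.
#' @param tails `"two"` (default) or `"one"` (each direction tested at the
#'   full `alpha`).
#' @param base_Ne Diploid size of the constant null (only sets the time
#'   scale; the null has no size changes). Defaults to the POD's own
#'   model.
#' @return An object of class `fusion_hyptest`: data frame with one row
#'   per statistic (`observed`, `p_lower`, `p_upper`, `alpha`,
#'   `inference`).
#' @export
test_pod <- function(pod, n_reps = 1000, seed = NULL, alpha = 0.05,
                     alpha_FS = 0.02, tails = c("two", "one"),
                     base_Ne = NULL) {
  tails <- match.arg(tails)
  if (is.null(base_Ne))
    base_Ne <- if (!is.null(pod$model)) pod$model$base_Ne else 10000
  prof <- sumstat_profile(pod)
  stats <- c("D", "Fstar", "FS", "R2", "Ystar", "ZnS")
  if (all(prof$n_defined == 0))
    stop("degenerate POD: no polymorphic locus")
  null <- estimate_distributions(pod, single_deme_model("constant", base_Ne),
                                 n_reps = n_reps, seed = seed)
  res <- lapply(stats, function(s) {
    obs <- prof$across_loci[[s]]
    vals <- null$values[[s]]
    a <- if (s == "FS") alpha_FS else alpha
    if (!is.finite(obs) || !length(vals)) {
      return(data.frame(statistic = s, observed = NA_real_,
                        p_lower = NA_real_, p_upper = NA_real_, alpha = a,
                        inference = "constancy"))
    }
    N <- length(vals)
    p_up <- (sum(vals >= obs) + 1) / (N + 1)
    p_lo <- (sum(vals <= obs) + 1) / (N + 1)
    cut <- if (tails == "two") a / 2 else a
    inference <- "constancy"
    if (p_up < cut) {
      # significantly positive D/F*/FS/Y*, significantly large R2/ZnS
      inference <- "decline"
    } else if (p_lo < cut) {
      inference <- "growth"
    }
    data.frame(statistic = s, observed = obs, p_lower = p_lo,
               p_upper = p_up, alpha = a, inference = inference)
  })
  out <- do.call(rbind, res)
  class(out) <- c("fusion_hyptest", "data.frame")
  out
}

#' @export
print.fusion_hyptest <- function(x, ...) {
  cat("POD versus constant-size null\n")
  df <- as.data.frame(x)
  df$flag <- ifelse(df$inference == "decline", "*decline*",
                    ifelse(df$inference == "growth", "*growth*", ""))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Count falsely inferred declines over replicate PODs
#'
#' Simulates `n_replicate_pods` independent datasets under a fusion
#' scenario, tests each against the constant-size null, and counts for
#' each statistic how many datasets yielded a (false) inference of
#' population decline.
#'
#' @param scenario A [fusion_scenario()] (or any demographic model).
#' @param comp A [dataset_composition()].
#' @param n_replicate_pods Number of independent PODs.
#' @param n_reps Null replicates per test.
#' @param seed Optional integer seed.
#' @param mm Mutation model for POD simulation.
#' @param ... Passed to [test_pod()] (e.g. `tails`).
#' @return Named integer vector of decline counts, one per statistic.
#' @export
decline_count <- function(scenario, comp, n_replicate_pods, n_reps = 1000,
                          seed = NULL, mm = mutation_model(), ...) {
  stats <- c("D", "Fstar", "FS", "R2", "Ystar", "ZnS")
  counts <- stats::setNames(integer(length(stats)), stats)
  if (n_replicate_pods < 1) return(counts)
  for (r in seq_len(n_replicate_pods)) {
    s <- if (is.null(seed)) NULL else derive_seed(seed, 7919L * r)
    pod <- simulate_pod(scenario, comp, mm, seed = s)
    tst <- test_pod(pod, n_reps = n_reps,
                    seed = if (is.null(s)) NULL else s + 1L, ...)
    counts <- counts + (tst$inference == "decline")
  }
  counts
}
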