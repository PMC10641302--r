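#' Estimate multi-locus null distributions of the six statistics
#'
#' For one pseudo-observed dataset and one demographic model, simulates
#' `n_reps` coalescent replicates of the whole multi-locus dataset, each
#' locus seeded with that locus's Watterson theta from the POD (locus
#' lengths enter only through theta; mutation follows the infinite-sites
#' model in coalescent time units). Each replicate contributes the
#' across-locus mean of every statistic; replicates where a statistic is
#' undefined at every locus are dropped for that statistic.
#'
#' @param pod A `haplotype_dataset`, or a list with elements `n_alleles`
#'   and `theta_w` (numeric, one per locus).
#' @param model A demographic model under which to simulate.
#' @param n_reps Number of replicates (canonically 1000).
#' @param seed Optional integer seed.
#' @param engine `"cpp"` (compiled, default) or `"R"` (the pure-R
#'   reference path via [simulate_null_replicate()]); both sample the same
#'   process.
#' @return An object of class `statistic_distributions`: a named list
#'   `values` of numeric vectors (one per statistic), plus `n_reps`,
#'   `n_dropped` and the model.
#' @export
estimate_distributions <- function(pod, model, n_reps = 1000, seed = NULL,
                                   engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (n_reps < 1) stop("n_reps must be >= 1")
  sd <- pod_seed_values(pod)
  if (all(sd$theta_w == 0)) stop("degenerate POD: theta is zero at every locus")
  validate_model(model)
  n <- sd$n_alleles
  M <- with_seed(seed, {
    if (engine == "cpp" && n <= 64) {
      ce <- coal_epochs(model)
      if (ce$fusion) {
        cpp_null_summaries(n, sd$theta_w, as.integer(n_reps), 1L, 0, 1,
                           ce$t_fuse, ce$t_div, ce$mix)
      } else {
        cpp_null_summaries(n, sd$theta_w, as.integer(n_reps), 0L,
                           ce$breaks, ce$sizes, 0, 0, 0)
      }
    } else {
      r_null_summaries(model, n, sd$theta_w, n_reps)
    }
  })
  stat <- stats_from_counts(n, M)
  rep_id <- rep(seq_len(n_reps), each = length(sd$theta_w))
  ndef <- rowsum(1 - is.na(stat), rep_id)
  tots <- rowsum(ifelse(is.na(stat), 0, stat), rep_id)
  means <- tots / ndef  # NaN where a statistic is undefined at all loci
  values <- lapply(colnames(stat), function(s) {
    v <- means[, s]
    v[is.finite(v)]
  })
  names(values) <- colnames(stat)
  structure(list(values = values, n_reps = n_reps,
                 n_dropped = n_reps - vapply(values, length, 0L),
                 model = model),
            class = "statistic_distributions")
}

# Pure-R engine: same per-locus summaries as the compiled path, computed
# from simulate_null_replicate() patterns.
r_null_summaries <- function(model, n, theta_w, n_reps) {
  out <- matrix(NA_real_, n_reps * length(theta_w), 7,
                dimnames = list(NULL, c("S", "K", "etaS", "Knos", "Hn",
                                        "R2", "ZnS")))
  row <- 0L
  for (r in seq_len(n_reps)) {
    pats <- simulate_null_replicate(model, n, theta_w, seed = NULL)
    for (mat in pats) {
      row <- row + 1L
      if (ncol(mat) == 0L) {
        out[row, ] <- c(0, 0, 0, 0, 1, NA, NA)
        next
      }
      sm <- site_summary(mat)
      out[row, ] <- c(sm$S, sm$K, sm$eta_S, sm$K_nosing, sm$H_N,
                      ramos_onsins_R2(sm), kelly_ZnS(mat))
    }
  }
  out
}

pod_seed_values <- function(pod) {
  if (inherits(pod, "haplotype_dataset")) {
    theta <- vapply(pod$loci, function(a) site_summary(a)$theta_w, 0)
    list(n_alleles = nrow(pod$loci[[1]]), theta_w = theta)
  } else if (is.list(pod) && !is.null(pod$n_alleles) && !is.null(pod$theta_w)) {
    list(n_alleles = pod$n_alleles, theta_w = pod$theta_w)
  } else stop("pod must be a haplotype_dataset or list(n_alleles, theta_w)")
}

#' @export
print.statistic_distributions <- function(x, ...) {
  cat(sprintf("Null distributions from %d replicates under %s\n", x$n_reps,
              if (inherits(x$model, "fusion_scenario")) "lineage fusion"
              else x$model$kind))
  for (s in names(x$values)) {
    ci <- central90_ci(x$values[[s]])
    cat(sprintf("  %-6s mean %8.4f  90%% CI [%8.4f, %8.4f]  (n = %d)\n",
                s, mean(x$values[[s]]), ci$lower, ci$upper,
                length(x$values[[s]])))
  }
  invisible(x)
}

#' Central 90% confidence interval of a simulated distribution
#'
#' The 5th and 95th empirical percentiles, with linear interpolation
#' between order statistics (quantile type 7), so intervals are
#' bit-reproducible.
#'
#' @param values Numeric vector of replicate values (>= 20), or a
#'   `statistic_distributions` object (then a data frame of intervals is
#'   returned).
#' @param level Central coverage (default 0.90).
#' @return A list with `lower` and `upper` (class `confidence_interval`),
#'   or a data frame with one row per statistic.
#' @examples
#' central90_ci(1:100)  # [5.95, 95.05]
#' @export
central90_ci <- function(values, level = 0.90) {
  if (inherits(values, "statistic_distributions")) {
    rows <- lapply(names(values$values), function(s) {
      ci <- central90_ci(values$values[[s]], level)
      data.frame(statistic = s, lower = ci$lower, upper = ci$upper)
    })
    return(do.call(rbind, rows))
  }
  if (length(values) < 20) stop("need at least 20 values for a stable CI")
  q <- stats::quantile(values, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  structure(list(lower = q[1], upper = q[2]), class = "confidence_interval")
}

#' @export
print.confidence_interval <- function(x, ...) {
  cat(sprintf("[%g, %g]\n", x$lower, x$upper))
  invisible(x)
}
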