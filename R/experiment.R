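#' Configuration for a full study run
#'
#' Bundles the scenario grid, dataset compositions, competing models,
#' replication settings and seed for the orchestration functions. By
#' default the canonical study design is used: 4 fusion scenarios, the 9
#' compositions (with four extra replicate rows of the 40-allele / 400-bp
#' / 50-locus composition, labelled POD-8b..e, giving 13 rows and 52
#' datasets in the full grid), 10 non-fusion models, 1000 null replicates
#' and 5 replicate PODs for the hypothesis-testing tables.
#'
#' @param scenarios Named list of fusion scenarios.
#' @param compositions Named list of dataset compositions.
#' @param nonfusion_models Named list of single-deme models.
#' @param n_reps Null-distribution replicates per (POD, model) cell.
#' @param n_replicate_pods Replicate PODs per scenario for the
#'   hypothesis-testing tables.
#' @param hyptest_composition Composition used for the hypothesis-testing
#'   tables (canonically the 40 x 400 x 50 row).
#' @param pod8_replicates Number of extra replicate rows of the POD-8
#'   composition appended to the grid (canonically 4, labels b..e).
#' @param mm Mutation model used to simulate PODs.
#' @param seed Integer seed for the whole run.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scenarios = canonical_fusion_scenarios(),
                              compositions = canonical_compositions(),
                              nonfusion_models = canonical_nonfusion_models(),
                              n_reps = 1000,
                              n_replicate_pods = 5,
                              hyptest_composition = canonical_compositions()[["POD-8"]],
                              pod8_replicates = 4,
                              mm = mutation_model(),
                              seed = 1L) {
  if (n_reps < 20) stop("n_reps must be >= 20")
  stopifnot(length(scenarios) >= 1, length(compositions) >= 1)
  structure(list(scenarios = scenarios, compositions = compositions,
                 nonfusion_models = nonfusion_models, n_reps = n_reps,
                 n_replicate_pods = n_replicate_pods,
                 hyptest_composition = hyptest_composition,
                 pod8_replicates = pod8_replicates, mm = mm,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# The grid rows: the configured compositions plus replicate POD-8 rows.
grid_rows <- function(config) {
  rows <- lapply(names(config$compositions), function(nm) {
    list(label = nm, comp = config$compositions[[nm]])
  })
  if (config$pod8_replicates > 0 && "POD-8" %in% names(config$compositions)) {
    extra <- lapply(seq_len(config$pod8_replicates), function(i) {
      list(label = paste0("POD-8", letters[i + 1L]),
           comp = config$compositions[["POD-8"]])
    })
    rows <- append(rows, extra, after = which(names(config$compositions) == "POD-8"))
  }
  rows
}

cell_seed <- function(config, scenario_i, row_i, salt = 0L) {
  derive_seed(config$seed, 1000L * scenario_i + 10L * row_i + salt)
}

#' Simulate the full POD grid and summarize its diversity
#'
#' For every (scenario, composition-row) cell, simulates one POD and
#' records its across-locus mean haplotype diversity and the sampling
#' variance of Hd across loci.
#'
#' @param config An [experiment_config()].
#' @return A data frame with one row per cell: `scenario`, `pod`,
#'   `n_alleles`, `locus_length`, `n_loci`, `Hd`, `Hd_var`.
#' @export
run_pod_grid <- function(config) {
  rows <- grid_rows(config)
  out <- list()
  for (si in seq_along(config$scenarios)) {
    for (ri in seq_along(rows)) {
      comp <- rows[[ri]]$comp
      pod <- simulate_pod(config$scenarios[[si]], comp, config$mm,
                          seed = cell_seed(config, si, ri))
      hd <- vapply(pod$loci, nei_Hd, 0)
      out[[length(out) + 1L]] <- data.frame(
        scenario = names(config$scenarios)[si], pod = rows[[ri]]$label,
        n_alleles = comp$n_alleles, locus_length = comp$locus_length,
        n_loci = comp$n_loci, Hd = mean(hd),
        Hd_var = if (length(hd) > 1) stats::var(hd) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Distinguishability of fusion across the whole design
#'
#' For each (scenario, composition) cell: simulates a POD under the
#' fusion scenario, estimates the six statistics' distributions under the
#' true fusion model and under every non-fusion model (all seeded with the
#' POD's per-locus theta), and records the unique proportion of the fusion
#' 90% CI per (statistic, model). Cells whose POD is monomorphic at every
#' locus are recorded as skipped with a warning rather than dropped
#' silently.
#'
#' @param config An [experiment_config()].
#' @param compositions Optional character vector restricting the
#'   composition rows (by name).
#' @return A long data frame: `scenario`, `pod`, `statistic`, `model`,
#'   `unique_proportion`, `overlap_case`.
#' @export
run_distinguishability <- function(config, compositions = NULL) {
  rows <- grid_rows(config)
  if (!is.null(compositions))
    rows <- Filter(function(r) r$label %in% compositions, rows)
  out <- list()
  for (si in seq_along(config$scenarios)) {
    scen <- config$scenarios[[si]]
    for (ri in seq_along(rows)) {
      pod <- simulate_pod(scen, rows[[ri]]$comp, config$mm,
                          seed = cell_seed(config, si, ri, salt = 1L))
      sd <- pod_seed_values(pod)
      if (all(sd$theta_w == 0)) {
        warning(sprintf("skipping monomorphic POD cell %s / %s",
                        names(config$scenarios)[si], rows[[ri]]$label))
        next
      }
      fuse_ci <- dist_cis(pod, scen, config, si, ri, salt = 2L)
      non_cis <- lapply(seq_along(config$nonfusion_models), function(mi)
        dist_cis(pod, config$nonfusion_models[[mi]], config, si, ri,
                 salt = 2L + mi))
      names(non_cis) <- names(config$nonfusion_models)
      grid <- distinguishability_grid(fuse_ci, non_cis)
      grid$scenario <- names(config$scenarios)[si]
      grid$pod <- rows[[ri]]$label
      out[[length(out) + 1L]] <- grid
    }
  }
  do.call(rbind, out)
}

dist_cis <- function(pod, model, config, si, ri, salt) {
  d <- estimate_distributions(pod, model, n_reps = config$n_reps,
                              seed = cell_seed(config, si, ri, salt))
  lapply(d$values, function(v)
    if (length(v) >= 20) central90_ci(v) else NULL)
}

#' Hypothesis-testing bias tables
#'
#' For each fusion scenario, simulates `n_replicate_pods` PODs of the
#' configured composition, tests each against the constant-size null, and
#' returns both the per-replicate observed statistics with significance
#' calls and the per-statistic counts of falsely inferred decline.
#'
#' @param config An [experiment_config()].
#' @param ... Passed to [test_pod()].
#' @return A list with `observed` (long data frame: scenario, replicate,
#'   statistic, observed, p_lower, p_upper, inference) and `decline_counts`
#'   (data frame: statistic x scenario counts).
#' @export
run_hyptest_tables <- function(config, ...) {
  obs <- list()
  for (si in seq_along(config$scenarios)) {
    for (r in seq_len(config$n_replicate_pods)) {
      s <- cell_seed(config, si, 99L, salt = r)
      pod <- simulate_pod(config$scenarios[[si]], config$hyptest_composition,
                          config$mm, seed = s)
      tst <- test_pod(pod, n_reps = config$n_reps, seed = s + 1L, ...)
      tst$scenario <- names(config$scenarios)[si]
      tst$replicate <- r
      obs[[length(obs) + 1L]] <- as.data.frame(tst)
    }
  }
  observed <- do.call(rbind, obs)
  counts <- stats::aggregate(inference ~ statistic + scenario,
                             data = observed,
                             FUN = function(x) sum(x == "decline"))
  names(counts)[names(counts) == "inference"] <- "n_decline"
  wide <- stats::reshape(counts, idvar = "statistic", timevar = "scenario",
                         direction = "wide")
  names(wide) <- sub("^n_decline\\.", "", names(wide))
  list(observed = observed, decline_counts = wide)
}
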