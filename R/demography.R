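#' Demographic models for the lineage-fusion study
#'
#' Two kinds of demographic history are modelled. A *fusion scenario*
#' describes two sister populations of constant diploid size `base_Ne` that
#' split `t_div` generations before present and merged back instantaneously
#' into a single panmictic deme `t_fuse` generations before present, with a
#' fraction `mix` of the merged pool contributed by the first population.
#' Sampling always occurs at the present day. A *single-deme model* is a
#' panmictic population whose size changes instantaneously at fixed times:
#' constant size, step growth or decline at `t_event`, or a bottleneck over
#' `[t_end, t_start]` (times in generations before present).
#'
#' The ratio of the pre-fusion divergence duration to the post-fusion
#' sampling lag, `(t_div - t_fuse) / t_fuse`, is the D:L ratio; larger
#' values make fusion easier to detect.
#'
#' @param base_Ne Diploid effective population size (individuals).
#' @param t_div Divergence time, generations before present.
#' @param t_fuse Fusion (merging) time, generations before present;
#'   `0 < t_fuse < t_div`.
#' @param mix Fraction of the merged gene pool contributed by population A,
#'   in `[0, 1]`.
#' @param sample_time Sampling time, generations before present (always 0 in
#'   the canonical study design).
#' @return An object of class `fusion_scenario`.
#' @examples
#' fs <- fusion_scenario(10000, t_div = 40000, t_fuse = 10000)
#' fs$dl_ratio
#' @export
fusion_scenario <- function(base_Ne, t_div, t_fuse, mix = 0.5, sample_time = 0) {
  x <- structure(
    list(base_Ne = base_Ne, t_div = t_div, t_fuse = t_fuse, mix = mix,
         sample_time = sample_time,
         dl_ratio = (t_div - t_fuse) / t_fuse),
    class = c("fusion_scenario", "demographic_model"))
  validate_model(x)
}

#' Single-deme demographic models
#'
#' @param kind One of `"constant"`, `"growth"`, `"decline"`, `"bottleneck"`.
#' @param base_Ne Diploid effective size of the population as sampled at
#'   the present day (and, for a bottleneck, also the size outside the
#'   bottleneck interval).
#' @param factor Fold change of the present-day size relative to the
#'   pre-event size for growth and decline (present = `base_Ne`,
#'   pre-event size = `base_Ne / factor`): growth by 2x means the
#'   population doubled at `t_event`; decline to 0.5x means it halved.
#'   For a bottleneck, the size *during* the interval is
#'   `factor * base_Ne`. Must be 1 for constant, > 1 for growth, in
#'   (0, 1) for decline and bottleneck.
#' @param t_event Time of the step change, generations before present
#'   (growth and decline).
#' @param t_start,t_end Bottleneck interval bounds, generations before
#'   present, with `t_start > t_end > 0`; the population is at
#'   `factor * base_Ne` between `t_end` and `t_start` and at `base_Ne`
#'   otherwise.
#' @return An object of class `single_deme_model`.
#' @examples
#' single_deme_model("decline", 10000, factor = 0.5, t_event = 10000)
#' @export
single_deme_model <- function(kind = c("constant", "growth", "decline", "bottleneck"),
                              base_Ne, factor = 1, t_event = NULL,
                              t_start = NULL, t_end = NULL) {
  kind <- match.arg(kind)
  x <- structure(
    list(kind = kind, base_Ne = base_Ne, factor = factor,
         t_event = t_event, t_start = t_start, t_end = t_end),
    class = c("single_deme_model", "demographic_model"))
  validate_model(x)
}

#' Validate a demographic model object
#'
#' Checks the structural invariants of a model and returns it invisibly;
#' any violation raises an error.
#'
#' @param x A `fusion_scenario` or `single_deme_model`.
#' @return `x`, invisibly (for `validate_model`); called for its side effect.
#' @export
validate_model <- function(x) UseMethod("validate_model")

#' @export
validate_model.fusion_scenario <- function(x) {
  stopifnot(is.numeric(x$base_Ne), length(x$base_Ne) == 1L)
  if (x$base_Ne < 2) stop("base_Ne must be at least 2")
  if (!(x$t_div > x$t_fuse && x$t_fuse > 0))
    stop("fusion scenario requires t_div > t_fuse > 0")
  if (x$mix < 0 || x$mix > 1) stop("mix must lie in [0, 1]")
  if (x$sample_time != 0) stop("sampling must occur at the present (sample_time = 0)")
  if (x$dl_ratio <= 0) stop("D:L ratio must be positive")
  invisible(x)
}

#' @export
validate_model.single_deme_model <- function(x) {
  if (x$base_Ne < 2) stop("base_Ne must be at least 2")
  switch(x$kind,
    constant = {
      if (x$factor != 1) stop("constant model requires factor = 1")
    },
    growth = {
      if (x$factor <= 1) stop("growth requires factor > 1")
      if (is.null(x$t_event) || x$t_event <= 0) stop("growth requires t_event > 0")
    },
    decline = {
      if (x$factor <= 0 || x$factor >= 1) stop("decline requires 0 < factor < 1")
      if (is.null(x$t_event) || x$t_event <= 0) stop("decline requires t_event > 0")
    },
    bottleneck = {
      if (x$factor <= 0 || x$factor >= 1) stop("bottleneck requires 0 < factor < 1")
      if (is.null(x$t_start) || is.null(x$t_end) || !(x$t_start > x$t_end && x$t_end > 0))
        stop("bottleneck requires t_start > t_end > 0")
    })
  invisible(x)
}

#' @export
print.fusion_scenario <- function(x, ...) {
  cat(sprintf(
    "Lineage fusion scenario: Ne = %g, t_div = %g, t_fuse = %g, mix = %g (D:L = %g)\n",
    x$base_Ne, x$t_div, x$t_fuse, x$mix, x$dl_ratio))
  invisible(x)
}

#' @export
print.single_deme_model <- function(x, ...) {
  extra <- switch(x$kind,
    constant = "",
    growth = sprintf(", factor = %g at t = %g", x$factor, x$t_event),
    decline = sprintf(", factor = %g at t = %g", x$factor, x$t_event),
    bottleneck = sprintf(", factor = %g over [%g, %g]", x$factor, x$t_end, x$t_start))
  cat(sprintf("Single-deme model (%s): Ne = %g%s\n", x$kind, x$base_Ne, extra))
  invisible(x)
}

#' Dataset composition: how sequencing resources are partitioned
#'
#' A composition fixes the number of sampled gene copies (`n_alleles`, two
#' per diploid individual), the alignment length per locus, and the number
#' of independent non-recombining phase-known loci. The canonical grid holds
#' the total amount of sequence at
#' `n_alleles * locus_length * n_loci = 800,000` bp per dataset.
#'
#' @param n_alleles Sampled gene copies (even, positive).
#' @param locus_length Base pairs per locus.
#' @param n_loci Number of loci.
#' @param alias Optional label (e.g. `"POD-3"`).
#' @return An object of class `dataset_composition`.
#' @export
dataset_composition <- function(n_alleles, locus_length, n_loci, alias = NULL) {
  if (n_alleles <= 0 || locus_length <= 0 || n_loci <= 0 ||
      n_alleles != round(n_alleles) || locus_length != round(locus_length) ||
      n_loci != round(n_loci))
    stop("composition fields must be positive integers")
  if (n_alleles %% 2 != 0) stop("n_alleles must be even (two per diploid)")
  structure(list(n_alleles = as.integer(n_alleles),
                 locus_length = as.integer(locus_length),
                 n_loci = as.integer(n_loci), alias = alias),
            class = "dataset_composition")
}

#' @export
print.dataset_composition <- function(x, ...) {
  cat(sprintf("%s: %d alleles x %d bp x %d loci (%g bp total)\n",
              if (is.null(x$alias)) "composition" else x$alias,
              x$n_alleles, x$locus_length, x$n_loci,
              as.numeric(x$n_alleles) * x$locus_length * x$n_loci))
  invisible(x)
}

#' Canonical lineage-fusion scenarios
#'
#' The four study scenarios: diploid `Ne = 10,000` throughout, fusion at
#' 10,000 generations before present with equal mixing, and divergence at
#' 20,000, 40,000, 60,000 or 100,000 generations, giving D:L ratios of
#' 1, 3, 5 and 9.
#'
#' @return A named list of four [fusion_scenario()] objects
#'   (`DL1`, `DL3`, `DL5`, `DL9`).
#' @export
canonical_fusion_scenarios <- function() {
  t_div <- c(20000, 40000, 60000, 100000)
  out <- lapply(t_div, function(td)
    fusion_scenario(base_Ne = 10000, t_div = td, t_fuse = 10000, mix = 0.5))
  names(out) <- paste0("DL", vapply(out, function(s) s$dl_ratio, 0))
  out
}

#' Canonical non-fusion models
#'
#' The ten competing single-deme histories, in plotting order: constant
#' size; growth by 2x, 3x, 4x; bottleneck to 0.5x, 1/3x, 0.25x; decline to
#' 0.5x, 1/3x, 0.25x. Growth and decline step at `1 * Ne = 10,000`
#' generations before present (coinciding with the fusion time); the
#' bottleneck runs from `2 * Ne` to `1 * Ne` generations before present.
#' The printed magnitudes 0.33x and 0.25x are stored as exact 1/3 and 1/4.
#'
#' @return A named list of ten [single_deme_model()] objects.
#' @export
canonical_nonfusion_models <- function() {
  Ne <- 10000
  shrink <- c(0.5, 1 / 3, 0.25)
  out <- c(
    list(constant = single_deme_model("constant", Ne)),
    lapply(c(2, 3, 4), function(f)
      single_deme_model("growth", Ne, factor = f, t_event = Ne)),
    lapply(shrink, function(f)
      single_deme_model("bottleneck", Ne, factor = f, t_start = 2 * Ne, t_end = Ne)),
    lapply(shrink, function(f)
      single_deme_model("decline", Ne, factor = f, t_event = Ne)))
  names(out) <- c("constant", "growth2x", "growth3x", "growth4x",
                  "bottleneck0.5x", "bottleneck0.33x", "bottleneck0.25x",
                  "decline0.5x", "decline0.33x", "decline0.25x")
  out
}

#' Canonical dataset compositions
#'
#' The nine partitions of 800,000 bp of sequencing resources across number
#' of sampled alleles, locus length, and number of loci.
#'
#' @return A named list of nine [dataset_composition()] objects,
#'   `POD-1` .. `POD-9`.
#' @export
canonical_compositions <- function() {
  tab <- list(
    c(10, 800, 100), c(10, 1600, 50), c(10, 8000, 10),
    c(20, 400, 100), c(20, 800, 50), c(20, 4000, 10),
    c(40, 200, 100), c(40, 400, 50), c(40, 2000, 10))
  out <- lapply(seq_along(tab), function(i)
    dataset_composition(tab[[i]][1], tab[[i]][2], tab[[i]][3],
                        alias = paste0("POD-", i)))
  names(out) <- paste0("POD-", seq_along(tab))
  out
}

#' Piecewise-constant population size looking backward in time
#'
#' Internal helper: expresses a single-deme model (or the merged-phase part
#' of a fusion scenario) as epochs of constant size. Epoch `i` spans
#' `[breaks[i], breaks[i + 1])` generations before present (the last break
#' is `Inf`) with diploid size `sizes[i]`.
#'
#' @noRd
size_epochs <- function(model) {
  Ne <- model$base_Ne
  switch(model$kind,
    constant = list(breaks = 0, sizes = Ne),
    # factor is the fold change of the present-day size relative to the
    # pre-event size; the sampled population is at base_Ne, so looking
    # backward the size jumps to base_Ne / factor at t_event
    growth = list(breaks = c(0, model$t_event), sizes = c(Ne, Ne / model$factor)),
    decline = list(breaks = c(0, model$t_event), sizes = c(Ne, Ne / model$factor)),
    bottleneck = list(breaks = c(0, model$t_end, model$t_start),
                      sizes = c(Ne, model$factor * Ne, Ne)))
}

#' Serialize a demographic model to JSON
#'
#' Writes all model fields (and class) as a JSON object so model grids can
#' be stored in plain-text configuration files; [model_from_json()] inverts
#' it.
#'
#' @param x A demographic model or `dataset_composition`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
model_to_json <- function(x, path = NULL) {
  fields <- unclass(x)
  fields$.class <- class(x)[1L]
  js <- jsonlite::toJSON(fields, auto_unbox = TRUE, null = "null", digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname model_to_json
#' @param json A JSON string or path to a JSON file produced by
#'   [model_to_json()].
#' @export
model_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  f <- jsonlite::fromJSON(paste(json, collapse = "\n"))
  switch(f$.class,
    fusion_scenario = fusion_scenario(f$base_Ne, f$t_div, f$t_fuse, f$mix,
                                      f$sample_time),
    single_deme_model = single_deme_model(f$kind, f$base_Ne, f$factor,
                                          f$t_event, f$t_start, f$t_end),
    dataset_composition = dataset_composition(f$n_alleles, f$locus_length,
                                              f$n_loci, f$alias),
    stop("unknown serialized class: ", f$.class))
}
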