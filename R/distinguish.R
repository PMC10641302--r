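#' Unique proportion of the fusion scenario's 90% CI
#'
#' Distinguishability of lineage fusion against one non-fusion model is
#' the fraction of the fusion scenario's central 90% CI that is *not*
#' covered by the competing model's 90% CI. Writing the fusion interval
#' `[FL, FU]` and the non-fusion interval `[NL, NU]`:
#' disjoint intervals give 1; a partial offset in the upper direction
#' contributes `(FU - NU) / (FU - FL)`; in the lower direction
#' `(NL - FL) / (FU - FL)`; a non-fusion CI nested inside the fusion CI
#' contributes the sum of both; a fusion CI inside the non-fusion CI gives
#' 0. Negative components are clipped at 0 and the result at 1, so the
#' measure is total. Intervals that merely touch are scored as disjoint.
#'
#' @param fuse A `confidence_interval` (or list with `lower`, `upper`) for
#'   the fusion scenario; must have positive width.
#' @param nonfuse The competing model's interval.
#' @return An object of class `distinguishability_result` with fields
#'   `unique_proportion` in `[0, 1]` and `overlap_case` (one of
#'   `disjoint`, `partial_upper`, `partial_lower`,
#'   `nested_nonfuse_inside`, `fuse_inside_nonfuse`, `identical`).
#' @examples
#' unique_proportion(list(lower = 0, upper = 10), list(lower = 2, upper = 9))
#' @export
unique_proportion <- function(fuse, nonfuse) {
  FL <- fuse$lower; FU <- fuse$upper
  NL <- nonfuse$lower; NU <- nonfuse$upper
  if (!(FU > FL)) stop("fusion CI has zero width: unique proportion undefined")
  if (NL >= FU || FL >= NU) {
    return(new_distinguishability(1, "disjoint"))
  }
  width <- FU - FL
  up <- min(max((FU - NU) / width, 0), 1)
  lo <- min(max((NL - FL) / width, 0), 1)
  if (FL == NL && FU == NU) {
    case <- "identical"
  } else if (up > 0 && lo > 0) {
    case <- "nested_nonfuse_inside"
  } else if (up > 0) {
    case <- "partial_upper"
  } else if (lo > 0) {
    case <- "partial_lower"
  } else {
    case <- "fuse_inside_nonfuse"
  }
  new_distinguishability(min(up + lo, 1), case)
}

new_distinguishability <- function(p, case) {
  structure(list(unique_proportion = p, overlap_case = case),
            class = "distinguishability_result")
}

#' @export
print.distinguishability_result <- function(x, ...) {
  cat(sprintf("unique proportion %.3f (%s)\n", x$unique_proportion,
              x$overlap_case))
  invisible(x)
}

#' Distinguishability grid: statistics by non-fusion models
#'
#' Applies [unique_proportion()] to every combination of statistic and
#' competing non-fusion model.
#'
#' @param fusion_CIs Named list (by statistic) of fusion-scenario CIs.
#' @param nonfusion_CIs Named list (by model) of named lists (by
#'   statistic) of CIs.
#' @return A data frame with columns `statistic`, `model`,
#'   `unique_proportion`, `overlap_case`; combinations with a missing or
#'   degenerate CI are kept as `NA` rows rather than dropped.
#' @export
distinguishability_grid <- function(fusion_CIs, nonfusion_CIs) {
  stats <- names(fusion_CIs)
  rows <- list()
  for (m in names(nonfusion_CIs)) {
    for (s in stats) {
      ci_f <- fusion_CIs[[s]]
      ci_n <- nonfusion_CIs[[m]][[s]]
      if (is.null(ci_f) || is.null(ci_n) || !(ci_f$upper > ci_f$lower)) {
        rows[[length(rows) + 1L]] <- data.frame(
          statistic = s, model = m, unique_proportion = NA_real_,
          overlap_case = NA_character_)
      } else {
        r <- unique_proportion(ci_f, ci_n)
        rows[[length(rows) + 1L]] <- data.frame(
          statistic = s, model = m, unique_proportion = r$unique_proportion,
          overlap_case = r$overlap_case)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$statistic <- factor(out$statistic, levels = stats)
  out$model <- factor(out$model, levels = names(nonfusion_CIs))
  out
}
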