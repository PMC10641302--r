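#' @useDynLib fusim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stream sub-seed so loci can be simulated independently
# (and in principle in parallel) without changing results. Kept below 2^31.
derive_seed <- function(seed, i) {
  s <- ((seed %% 2147483647) * 48271 + i * 16807 + 12345) %% 2147483647
  as.integer(s)
}

#' Simulate a coalescent genealogy under a demographic model
#'
#' Runs the standard (structured) coalescent backward in time with
#' piecewise-constant population sizes. For a single-deme model the
#' pairwise coalescence rate at time `t` is `1 / (2 N(t))` per pair (sizes
#' in diploid individuals). For a fusion scenario, lineages coalesce in one
#' panmictic deme of size `base_Ne` from the present back to `t_fuse`; each
#' lineage still uncoalesced at `t_fuse` is then independently assigned to
#' sister population A with probability `mix` (else B); between `t_fuse`
#' and `t_div` coalescence happens only within a sister population (each of
#' size `base_Ne`); at `t_div` the demes merge into the single ancestral
#' deme.
#'
#' @param model A [fusion_scenario()] or [single_deme_model()].
#' @param n_alleles Number of sampled gene copies (>= 2), all at time 0.
#' @param seed Optional integer seed (the caller's RNG stream is restored
#'   afterwards).
#' @return An object of class `genealogy`: a rooted ultrametric binary tree
#'   with fields `n`, `parent` (index of each node's parent, `NA` at the
#'   root), `time` (node times in generations before present, 0 at leaves),
#'   and `leaf_labels`. Nodes `1..n` are leaves; internal nodes
#'   `n+1..2n-1` are in increasing time order (the root is node `2n - 1`).
#' @examples
#' g <- simulate_genealogy(single_deme_model("constant", 1000), 4, seed = 1)
#' max(g$time)  # TMRCA in generations
#' @export
simulate_genealogy <- function(model, n_alleles, seed = NULL) {
  validate_model(model)
  if (n_alleles < 2) stop("n_alleles must be >= 2")
  with_seed(seed, {
    if (inherits(model, "fusion_scenario")) {
      sim_genealogy_fusion(model, n_alleles)
    } else {
      ep <- size_epochs(model)
      sim_genealogy_epochs(ep$breaks, ep$sizes, n_alleles)
    }
  })
}

# Shared state builder: coalesce `active` node ids in a single pool of
# piecewise-constant size from time t0 until t_max (Inf = until MRCA).
# `st` is an environment holding parent/time/next_node.
coalesce_pool <- function(st, active, t0, t_max, breaks, sizes) {
  t <- t0
  e <- findInterval(t, breaks)
  repeat {
    k <- length(active)
    if (k <= 1L || t >= t_max) break
    rate <- k * (k - 1) / 2 / (2 * sizes[e])
    w <- stats::rexp(1L, rate)
    epoch_end <- if (e < length(breaks)) breaks[e + 1L] else Inf
    boundary <- min(epoch_end, t_max)
    if (t + w >= boundary) {
      t <- boundary
      if (boundary == epoch_end && epoch_end < t_max) e <- e + 1L
      next
    }
    t <- t + w
    pair <- sample.int(k, 2L)
    node <- st$next_node
    st$next_node <- node + 1L
    st$time[node] <- t
    st$parent[active[pair]] <- node
    active <- c(active[-pair], node)
  }
  list(active = active, t = t)
}

sim_genealogy_epochs <- function(breaks, sizes, n) {
  st <- new.env(parent = emptyenv())
  st$parent <- rep(NA_integer_, 2L * n - 1L)
  st$time <- numeric(2L * n - 1L)
  st$next_node <- n + 1L
  coalesce_pool(st, seq_len(n), 0, Inf, breaks, sizes)
  new_genealogy(n, st$parent, st$time)
}

sim_genealogy_fusion <- function(model, n) {
  Ne <- model$base_Ne
  st <- new.env(parent = emptyenv())
  st$parent <- rep(NA_integer_, 2L * n - 1L)
  st$time <- numeric(2L * n - 1L)
  st$next_node <- n + 1L
  # merged phase: present back to t_fuse
  ph1 <- coalesce_pool(st, seq_len(n), 0, model$t_fuse, 0, Ne)
  active <- ph1$active
  if (length(active) > 1L) {
    # divergence phase: two isolated sister demes of size Ne
    in_A <- stats::runif(length(active)) < model$mix
    t <- model$t_fuse
    repeat {
      kA <- sum(in_A); kB <- sum(!in_A)
      rA <- kA * (kA - 1) / 2 / (2 * Ne)
      rB <- kB * (kB - 1) / 2 / (2 * Ne)
      if (rA + rB == 0 || t >= model$t_div) break
      w <- stats::rexp(1L, rA + rB)
      if (t + w >= model$t_div) { t <- model$t_div; break }
      t <- t + w
      pick_A <- stats::runif(1L) < rA / (rA + rB)
      pool <- which(in_A == pick_A)
      pair <- pool[sample.int(length(pool), 2L)]
      node <- st$next_node
      st$next_node <- node + 1L
      st$time[node] <- t
      st$parent[active[pair]] <- node
      keep <- setdiff(seq_along(active), pair)
      active <- c(active[keep], node)
      in_A <- c(in_A[keep], pick_A)
    }
    # ancestral merged deme
    if (length(active) > 1L)
      coalesce_pool(st, active, model$t_div, Inf, 0, Ne)
  }
  new_genealogy(n, st$parent, st$time)
}

new_genealogy <- function(n, parent, time) {
  structure(list(n = n, parent = parent, time = time,
                 leaf_labels = seq_len(n)),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("Coalescent genealogy: %d leaves, TMRCA = %.1f generations\n",
              x$n, max(x$time)))
  invisible(x)
}

#' Total branch length of a genealogy, in generations
#' @param g A `genealogy`.
#' @return Sum of all branch lengths.
#' @export
tree_length <- function(g) {
  notroot <- seq_len(2L * g$n - 2L)
  sum(g$time[g$parent[notroot]] - g$time[notroot])
}

#' Convert a genealogy to an \pkg{ape} \code{phylo} tree
#'
#' @param x A `genealogy`.
#' @param ... Unused.
#' @return An object of class `phylo` with branch lengths in generations.
#' @importFrom ape as.phylo
#' @exportS3Method ape::as.phylo
as.phylo.genealogy <- function(x, ...) {
  n <- x$n
  # ape convention: tips 1..n, root n+1; our internal nodes are in
  # increasing time order so the root (node 2n-1) maps to n+1.
  remap <- function(id) ifelse(id <= n, id, 3L * n - id)
  notroot <- seq_len(2L * n - 2L)
  edge <- cbind(remap(x$parent[notroot]), remap(notroot))
  len <- x$time[x$parent[notroot]] - x$time[notroot]
  tr <- list(edge = edge, edge.length = len, tip.label = paste0("t", seq_len(n)),
             Nnode = n - 1L)
  class(tr) <- "phylo"
  stats::reorder(tr)
}
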