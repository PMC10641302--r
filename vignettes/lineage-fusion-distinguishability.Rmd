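---
title: "Distinguishing lineage fusion from population decline: models, statistics, and design choices"
author: "fusim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing lineage fusion from population decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Lineage fusion is the complete merging of two long-isolated populations
into a single panmictic gene pool, with neither parental lineage surviving
separately. A sample taken today from the fused population carries two
kinds of coalescent signal: recent common ancestry within the merged deme,
and a residue of deep between-lineage divergence. The same
excess-of-old-branches pattern is produced by population decline, which is
why fusion is so easily misdiagnosed. `fusim` implements the full
simulation machinery needed to ask *when* fusion is distinguishable from
constant size, growth, bottleneck, and decline, using standard
neutrality-test summary statistics.

## The demographic models

A fusion scenario is parametrized by the diploid effective size
(`base_Ne = 10,000` throughout the canonical design), the divergence time
`t_div`, the merge time `t_fuse = 10,000` generations, and the mixing
fraction (0.5: both parental populations contribute equally). The
informative quantity is the D:L ratio, `(t_div - t_fuse) / t_fuse`: the
duration of divergence relative to the post-fusion lag before sampling.
The canonical grid uses `t_div` of 20k, 40k, 60k and 100k generations,
i.e. D:L of 1, 3, 5 and 9. Backward in time the simulator coalesces
lineages panmictically until `t_fuse`, assigns each surviving lineage
independently to a parental population with probability `mix` (the natural
backward-time reading of equal mixing), lets them coalesce only within
their population until `t_div`, and then merges the demes.

The ten competing single-deme histories are constant size; step growth by
2x, 3x or 4x at `1 Ne` generations; a bottleneck at `factor` times base
size between `2 Ne` and `1 Ne` generations; and step decline to 0.5x,
1/3x or 0.25x at `1 Ne` generations (the printed 0.33x/0.25x magnitudes
are stored as exact thirds and quarters).

**Which size is `base_Ne`?** For growth and decline we take `base_Ne` to
be the *present-day* (sampled) size, so a 0.25x decline means the
population was `base_Ne / 0.25 = 40,000` before the event. This follows
the coalescent-simulator convention in which theta refers to the sampled
deme (`theta = 4 N0 mu`), makes all competing hypotheses share the
present-day population they purport to explain, and — decisively — it is
the only reading that reproduces the benchmark phenomenon this
package targets: under it
a severe decline produces multi-locus mean Tajima's D and Fu's FS
distributions nearly coincident with those of a D:L = 9 fusion (we
measure decline 0.25x: D about 0.67, FS about 4.1 versus fusion D:L = 9:
D about 0.67, FS about 3.3), together with the reported positive
correlation between decline severity and confusability at D:L of 3 and
above. Under the alternative reading (ancestral size fixed at `base_Ne`,
present size `factor * base_Ne`), a 0.25x decline is nearly
indistinguishable from constancy on these time scales and fusion would be
trivially separable from decline, which contradicts the phenomenon the
package exists to study. One consequence we accept: at D:L = 1 a severe
decline separates from the (nearly neutral) fusion signature in the
*opposite* direction, so the D:L = 1 column of the distinguishability
grid is not uniformly low in our reproduction.

## Mutation model

Pseudo-observed datasets (PODs) are finite-site HKY simulations:
equal base frequencies, transition/transversion ratio 2 (HKY
`kappa = 4` under equal frequencies), 10% invariant sites, two discrete
gamma rate categories, and `mu = 1e-7` substitutions/site/generation.
Rate categories use the discrete-gamma mean method and average to 1 over
variable sites, so the genome-wide mean rate is `0.9 mu`. The gamma shape
is not pinned by the canonical design; we default to 1.0 and expose it in
`mutation_model()`. Sensitivity of haplotype-diversity-scale quantities
to the shape is small (about 0.02 between shape 1 and no heterogeneity in
our checks).

The distribution-estimation path deliberately uses a different mutation
model, mirroring the asymmetric toolchains of the classical workflow
(ABC-style finite-site data generation; "given theta" distribution
estimation):
null replicates are seeded with each locus's Watterson theta and mutated
under the infinite-sites model in coalescent time units (rate `theta / 2`
per lineage per `2 Ne` generations), which is the "given theta"
convention of the classical multi-locus coalescent machinery. Event times
are converted to coalescent units with the model's `base_Ne`; theta only
scales mutation.

## Summary statistics

Per locus the package computes Tajima's D, Fu and Li's F*, Fu's FS,
Ramos-Onsins and Rozas's R2, Achaz's Y*, Kelly's ZnS, and Nei's
haplotype diversity, then averages across loci. Conventions worth
spelling out:

* **Undefined values.** Statistics are undefined at `S = 0` (fewer than
  two biallelic sites for ZnS; no non-singleton sites for Y*); undefined
  loci are excluded from across-locus means and the exclusion count is
  reported. Multi-allelic columns count once toward `S`, contribute all
  state mismatches to pairwise differences, and are excluded from ZnS
  pairs.
* **Singletons** are columns where exactly one sequence carries a
  minority state present once (the folded definition, since no outgroup
  is simulated); F* and Y* use the starred variants accordingly.
* **FS** feeds the per-locus pairwise-difference estimate of theta into
  the Ewens sampling formula; the haplotype-number tail probability is
  computed with unsigned Stirling numbers of the first kind entirely in
  log space, so samples of 100+ alleles cannot overflow. The
  implementation is tested to 1e-9 against brute-force enumeration of
  integer partitions for n up to 8.
* **Variance constants.** Tajima's D uses the classical constants, which
  we verify to machine precision against an independent route: the exact
  covariance matrix of the site frequency spectrum. F* uses the field's
  standard corrected constants; our exact-covariance check shows these
  understate the true variance of the numerator by 10-15% in the
  theta-squared term — a property of the classical derivation that we
  keep for comparability, since all hypothesis tests in the package are
  empirical (the normalization cancels between observed and null). Y* is
  normalized with the exact covariances directly. At `n = 4` the
  singleton-free pi and Watterson estimators coincide, so Y* is
  inherently undefined there.

## Null distributions, distinguishability, and hypothesis tests

For one POD and one demographic model, `estimate_distributions()` runs
(canonically) 1000 replicates of the whole multi-locus dataset, each locus
seeded with that locus's Watterson theta, and collects the across-locus
mean of each statistic. Replicates where a statistic is undefined at every
locus are dropped and counted. The central 90% CI uses linear
interpolation between order statistics (quantile type 7), making intervals
bit-reproducible. The inner loop is compiled (clades as 64-bit masks,
so up to 64 sampled alleles; the pure-R `simulate_null_replicate()`
implements the identical process and the two are cross-checked
distributionally in the tests).

Distinguishability of fusion against a competitor is the fraction of the
fusion scenario's 90% CI not covered by the competitor's 90% CI, computed
by the published case analysis (disjoint = 1; upper/lower partial offsets;
nested competitor = sum of both tails; fusion nested inside competitor =
0, the reading we adopt for the one case the published rule leaves
implicit). Touching
intervals are a measure-zero tie scored as disjoint; negative components
are clipped so the formula is total. The implementation is verified
exactly against an interval-measure oracle.

The hypothesis-testing framework tests each POD against a constant-size
null: empirical `(r + 1) / (N + 1)` tail probabilities, two-sided with
`alpha / 2` per tail (`alpha = 0.05`; 0.02 for FS), with a one-tailed
variant exposed because the original tool's convention is not
documented. Significantly positive D, F*, FS, Y* or large R2, ZnS are
read as decline; the mirror image as growth.

## What the generator emulates, and what it does not

The synthetic data are phase-known, non-recombining, selectively neutral
autosomal loci with free recombination between loci and no sequencing or
phasing error — the idealization the canonical design calls for. Passing
tests therefore demonstrate correctness of the coalescent machinery and
statistics, and reproduction of the benchmark simulation results; they do
not establish how fusion detection degrades with intralocus
recombination, gene flow during divergence, unequal mixing, selection, or
phasing error, all of which are explicit non-goals.

Reproduction quality has one documented limit: for some compositions the
published per-POD haplotype diversities are offset from ours by up to
about 0.06 with a compressed spread across D:L ratios. We cross-checked
our simulator against an independent coalescent implementation (msprime)
under the identical demography and mutation model and the two agree with
each other, not with the printed cells; we attribute the offset to
internals of the original data-generation toolchain that are not
documented. All acceptance-level comparisons pass at their stochastic
tolerances regardless.

## Numerical and design choices

* Seeds: every simulating function takes a `seed` and restores the
  caller's RNG stream; multi-locus runs derive deterministic per-locus
  sub-seeds so results are reproducible and parallelizable in principle.
* Degenerate inputs: all-monomorphic PODs are rejected as degenerate
  when seeding null distributions; zero-width fusion CIs are an error in
  the overlap rule; `n_alleles` below 2, invalid model invariants
  (`t_div <= t_fuse`, factors on the wrong side of 1, inverted
  bottleneck bounds) all fail validation loudly.
* Problem sizes: the shipped tests reproduce the published tables at
  reduced but statistically honest scales — e.g. 20 replicate PODs for
  the D:L = 9 decline-probability check, 10 for Hd cells, 500 PODs for
  the type-I calibration, a 200-replicate profile for the
  distinguishability grid — chosen so each comparison retains at least
  3-sigma-style resolution. The full canonical design (1000 replicates,
  every scenario by composition cell) runs through the same
  `experiment_config()` interface by changing two arguments.
* The hypothesis-test calibration uses a 10-allele, 1000-bp, 10-locus
  composition: long enough loci that per-locus theta estimates are
  informative (very low-theta loci make the theta-seeded test visibly
  conservative), small enough that 500 PODs run in about two minutes.

## Known limitations

Fusion of more than two populations, unequal mixing, migration during
divergence, and continuous (exponential) size change are out of scope.
The compiled path limits samples to 64 alleles per locus (the pure-R path
has no such limit). Extended Bayesian skyline analyses require an external MCMC toolchain
and are out of scope.
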