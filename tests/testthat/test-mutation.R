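test_that("the HKY transition matrix matches the K80 closed form for equal frequencies", {
  mm <- mutation_model()  # ts/tv = 2 => kappa = 4
  mach <- fusim:::hky_machinery(mm)
  # independent closed form: alpha + 2 beta = 1, alpha / (2 beta) = R
  R <- 2
  beta <- 1 / (2 * (R + 1)); alpha <- R / (R + 1)
  for (d in c(0.01, 0.1, 0.5, 2)) {
    P <- fusim:::hky_P(mach, d)
    p_same <- 0.25 + 0.25 * exp(-4 * beta * d) +
      0.5 * exp(-2 * (alpha + beta) * d)
    p_ts <- 0.25 + 0.25 * exp(-4 * beta * d) -
      0.5 * exp(-2 * (alpha + beta) * d)
    p_tv <- 0.25 - 0.25 * exp(-4 * beta * d)
    expect_equal(unname(diag(P)), rep(p_same, 4), tolerance = 1e-10)
    expect_equal(P[1, 3], p_ts, tolerance = 1e-10)  # A -> G
    expect_equal(P[2, 4], p_ts, tolerance = 1e-10)  # C -> T
    expect_equal(P[1, 2], p_tv, tolerance = 1e-10)  # A -> C
    expect_true(all(abs(rowSums(P) - 1) < 1e-12))
  }
})

test_that("discrete gamma categories average to rate 1", {
  for (shape in c(0.3, 1, 5)) for (k in c(1, 2, 4, 8)) {
    r <- discrete_gamma_rates(shape, k)
    expect_length(r, k)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) >= 0))
  }
})

test_that("zero mutation rate yields identical sequences", {
  g <- simulate_genealogy(single_deme_model("constant", 1e4), 6, seed = 5)
  aln <- apply_mutations(g, mutation_model(mu = 0), 100, seed = 6)
  expect_equal(dim(aln), c(6, 100))
  expect_equal(site_summary(aln)$S, 0)
  expect_equal(nei_Hd(aln), 0)
})

test_that("segregating sites match Watterson's expectation under the constant model", {
  # E[S] ~= theta_locus * a_n with theta_locus = 4 Ne mu L (1 - p_inv)
  Ne <- 10000; L <- 1000; n <- 10
  mm <- mutation_model()
  theta <- 4 * Ne * mm$mu * L * (1 - mm$prop_invariant)
  expected <- theta * sum(1 / (1:(n - 1)))
  set.seed(31)
  S <- replicate(400, {
    g <- simulate_genealogy(single_deme_model("constant", Ne), n)
    site_summary(apply_mutations(g, mm, L))$S
  })
  se <- sd(S) / sqrt(length(S))
  # finite-site collisions bias S down slightly; stay within 3 MC SE + 2%
  expect_lt(abs(mean(S) - expected), 3 * se + 0.02 * expected)
})

test_that("invariant sites never vary and transitions outnumber transversions 2:1", {
  mm <- mutation_model()
  g <- simulate_genealogy(single_deme_model("constant", 2e4), 20, seed = 8)
  aln <- apply_mutations(g, mm, 4000, seed = 9)
  varying <- mean(apply(aln, 2, function(col) length(unique(col)) > 1))
  expect_lte(varying, 1 - mm$prop_invariant)
  # classify biallelic differences
  purines <- c("A", "G")
  types <- apply(aln, 2, function(col) {
    st <- unique(col)
    if (length(st) != 2) return(NA)
    if (sum(st %in% purines) == 1) "tv" else "ts"
  })
  ts <- sum(types == "ts", na.rm = TRUE); tv <- sum(types == "tv", na.rm = TRUE)
  expect_gt(ts / tv, 1.4)  # ratio 2 with multinomial noise
  expect_lt(ts / tv, 2.8)
})

test_that("simulate_pod respects composition, provenance and seeding", {
  comp <- dataset_composition(6, 300, 3)
  pod <- simulate_pod(canonical_fusion_scenarios()$DL3, comp, seed = 21)
  expect_s3_class(pod, "haplotype_dataset")
  expect_length(pod$loci, 3)
  expect_true(all(vapply(pod$loci, nrow, 0L) == 6))
  expect_true(all(vapply(pod$loci, ncol, 0L) == 300))
  expect_equal(rownames(pod$loci[[1]])[1:3],
               c("sample1_allele1", "sample1_allele2", "sample2_allele1"))
  pod2 <- simulate_pod(canonical_fusion_scenarios()$DL3, comp, seed = 21)
  expect_identical(pod$loci, pod2$loci)
  one <- simulate_pod(canonical_fusion_scenarios()$DL3,
                      dataset_composition(4, 50, 1), seed = 2)
  expect_length(one$loci, 1)
})

test_that("null replicates reproduce Watterson and pairwise-difference expectations", {
  const <- single_deme_model("constant", 10000)
  set.seed(13)
  S <- replicate(1200, ncol(simulate_null_replicate(const, 10, 5)[[1]]))
  a9 <- sum(1 / (1:9))
  expect_lt(abs(mean(S) - 5 * a9), 3 * sd(S) / sqrt(length(S)))
  # E[pairwise difference] = theta for n = 2
  set.seed(14)
  K <- replicate(1500, {
    m <- simulate_null_replicate(const, 2, 1)[[1]]
    if (ncol(m) == 0) 0 else sum(m[1, ] != m[2, ])
  })
  expect_lt(abs(mean(K) - 1), 3 * sd(K) / sqrt(length(K)))
  # theta = 0 gives S = 0 always
  expect_equal(ncol(simulate_null_replicate(const, 5, 0, seed = 1)[[1]]), 0)
  expect_error(simulate_null_replicate(const, 5, -1), "non-negative")
})
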