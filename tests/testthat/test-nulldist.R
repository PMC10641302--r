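test_that("central CI percentiles match direct order statistics", {
  expect_equal(unclass(central90_ci(1:100))[c("lower", "upper")],
               list(lower = 5.95, upper = 95.05))
  set.seed(3)
  for (rep in 1:20) {
    x <- rnorm(sample(20:200, 1))
    ci <- central90_ci(x)
    expect_equal(ci$lower, oracle_percentile(x, 0.05), tolerance = 1e-13)
    expect_equal(ci$upper, oracle_percentile(x, 0.95), tolerance = 1e-13)
  }
  const <- central90_ci(rep(3.5, 25))
  expect_equal(c(const$lower, const$upper), c(3.5, 3.5))
  # translation equivariance
  x <- rnorm(50)
  a <- central90_ci(x); b <- central90_ci(x + 2.5)
  expect_equal(b$lower, a$lower + 2.5)
  expect_equal(b$upper, a$upper + 2.5)
  expect_error(central90_ci(1:10), "at least 20")
})

test_that("CI bounds never decrease when a high value is appended", {
  set.seed(4)
  x <- rnorm(60)
  ci <- central90_ci(x)
  ci2 <- central90_ci(c(x, max(x) + 1))
  expect_gte(ci2$lower, ci$lower)
  expect_gte(ci2$upper, ci$upper)
})

test_that("null distributions are reproducible, sized, and centered sensibly", {
  pod <- list(n_alleles = 10, theta_w = rep(5, 10))
  const <- single_deme_model("constant", 10000)
  d1 <- estimate_distributions(pod, const, n_reps = 400, seed = 8)
  d2 <- estimate_distributions(pod, const, n_reps = 400, seed = 8)
  expect_identical(d1$values, d2$values)
  expect_true(all(vapply(d1$values, length, 0L) <= 400))
  ci <- central90_ci(d1$values$D)
  expect_lt(ci$lower, 0)
  expect_gt(ci$upper, 0)
  one <- estimate_distributions(pod, const, n_reps = 1, seed = 1)
  expect_true(all(vapply(one$values, length, 0L) <= 1))
})

test_that("degenerate (all-monomorphic) PODs are rejected", {
  pod <- list(n_alleles = 10, theta_w = rep(0, 5))
  expect_error(estimate_distributions(pod, single_deme_model("constant", 1e4)),
               "degenerate POD")
})

test_that("compiled and pure-R engines draw from the same distribution", {
  pod <- list(n_alleles = 12, theta_w = rep(4, 4))
  dl5 <- canonical_fusion_scenarios()$DL5
  dc <- estimate_distributions(pod, dl5, n_reps = 500, seed = 21,
                               engine = "cpp")
  dr <- estimate_distributions(pod, dl5, n_reps = 500, seed = 22,
                               engine = "R")
  for (s in c("D", "FS", "ZnS")) {
    ks <- suppressWarnings(ks.test(dc$values[[s]], dr$values[[s]]))
    expect_gt(ks$p.value, 0.005)
  }
  # and for a bottleneck single-deme model
  bn <- canonical_nonfusion_models()$bottleneck0.5x
  dc2 <- estimate_distributions(pod, bn, n_reps = 400, seed = 31,
                                engine = "cpp")
  dr2 <- estimate_distributions(pod, bn, n_reps = 400, seed = 32,
                                engine = "R")
  ks2 <- suppressWarnings(ks.test(dc2$values$D, dr2$values$D))
  expect_gt(ks2$p.value, 0.005)
})

test_that("fusion nulls shift FS upward relative to the constant model", {
  pod <- list(n_alleles = 20, theta_w = rep(2, 10))
  fus <- estimate_distributions(pod, canonical_fusion_scenarios()$DL9,
                                n_reps = 300, seed = 41)
  con <- estimate_distributions(pod, single_deme_model("constant", 1e4),
                                n_reps = 300, seed = 42)
  expect_gt(mean(fus$values$FS), mean(con$values$FS) + 0.5)
})
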