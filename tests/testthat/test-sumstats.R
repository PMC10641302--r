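toy_split <- rbind(rep("A", 4), rep("A", 4),
                   c("T", "T", "T", "A"), c("T", "T", "T", "A"))
toy_singleton <- rbind(rep("A", 4), rep("A", 4), rep("A", 4),
                       c("A", "A", "A", "T"))
toy_private <- rbind(c("T", "A", "A", "A"), c("A", "T", "A", "A"),
                     c("A", "A", "T", "A"), c("A", "A", "A", "T"))

test_that("site summaries of the toy alignments match direct enumeration", {
  s <- site_summary(toy_split)
  expect_equal(s$S, 3)
  expect_equal(s$K, 2.0)            # 12 differing pairs-of-columns over 6 pairs
  expect_equal(s$H_N, 2)
  expect_equal(s$eta_S, 0)
  expect_equal(s$theta_w, 3 / (1 + 1 / 2 + 1 / 3))
  s2 <- site_summary(toy_singleton)
  expect_equal(s2$S, 1)
  expect_equal(s2$eta_S, 1)
  expect_equal(s2$K, 0.5)
  expect_equal(s2$H_N, 2)
  mono <- site_summary(matrix("G", 4, 7))
  expect_equal(mono$S, 0)
  expect_equal(mono$K, 0)
  expect_equal(mono$H_N, 1)
  expect_equal(mono$eta_S, 0)
})

test_that("statistics reproduce frozen values on the toy alignments", {
  s <- site_summary(toy_split)
  expect_equal(tajima_D(s), 2.0118695404, tolerance = 1e-9)
  expect_equal(fu_li_F_star(s), 1.7990814523, tolerance = 1e-9)
  expect_equal(kelly_ZnS(toy_split), 1.0)        # complete LD
  expect_equal(nei_Hd(toy_split), 2 / 3)
  expect_true(is.na(achaz_Y_star(s)))  # at n = 4 the two singleton-free
                                       # estimators coincide: Y* degenerate
  sp <- site_summary(toy_private)
  expect_equal(ramos_onsins_R2(sp), 0)           # U_i = 1 = K/2 for all i
  expect_equal(fu_li_F_star(sp), -0.7205248257, tolerance = 1e-9)
  expect_true(is.na(achaz_Y_star(sp)))           # all sites are singletons
  expect_true(fu_li_F_star(sp) < 0 && fu_li_F_star(s) > 0)
  # two sites with phases 1100 and 1010: r^2 = 0
  expect_equal(kelly_ZnS(cbind(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))), 0)
  expect_true(is.na(kelly_ZnS(matrix("A", 4, 3))))
  # all-distinct haplotypes force Hd = 1
  expect_equal(nei_Hd(toy_private), 1)
})

test_that("every statistic matches its independent reference implementation on random alignments", {
  set.seed(2024)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    L <- sample(10:50, 1)
    aln <- random_alignment(n, L)
    s <- site_summary(aln)
    o <- oracle_site_stats(aln)
    expect_equal(s$S, o$S)
    expect_equal(s$K, o$K, tolerance = 1e-12)
    expect_equal(s$eta_S, o$eta_S)
    expect_equal(s$H_N, o$H_N)
    expect_equal(s$U, o$U)
    expect_equal(tajima_D(s), oracle_tajima_D(aln), tolerance = 1e-6)
    expect_equal(fu_li_F_star(s), oracle_fu_li_Fstar(aln), tolerance = 1e-6)
    expect_equal(ramos_onsins_R2(s), oracle_R2(aln), tolerance = 1e-6)
    expect_equal(kelly_ZnS(aln), oracle_ZnS(aln), tolerance = 1e-6)
    expect_equal(nei_Hd(aln), oracle_Hd(aln), tolerance = 1e-12)
    if (s$S > 0 && s$n <= 8) {
      spr <- oracle_ewens_tail(s$n, s$theta_pi, s$H_N)
      expect_equal(fu_FS(s), log(spr / (1 - spr)), tolerance = 1e-7)
    }
  }
})

test_that("all statistics are invariant to relabelling sequences", {
  set.seed(9)
  aln <- random_alignment(8, 40)
  perm <- aln[sample(8), ]
  s1 <- site_summary(aln); s2 <- site_summary(perm)
  for (f in list(tajima_D, fu_li_F_star, fu_FS, achaz_Y_star))
    expect_equal(f(s1), f(s2))
  expect_equal(ramos_onsins_R2(s1), ramos_onsins_R2(s2))
  expect_equal(kelly_ZnS(aln), kelly_ZnS(perm))
  expect_equal(nei_Hd(aln), nei_Hd(perm))
})

test_that("Tajima's classical constants agree with the exact spectrum covariance route", {
  # independent derivation: Var(K - S/a1) = alpha theta + beta theta^2 with
  # alpha, beta from the Fu (1995) covariance matrix
  for (n in c(4, 7, 10, 23, 40)) {
    cst <- fusim:::stat_constants(n)
    sigma <- fu_sigma(n)
    i <- 1:(n - 1)
    w <- i * (n - i) / (n * (n - 1) / 2) - 1 / cst$a1
    vc <- fusim:::spectrum_var_coefs(w, sigma)
    expect_equal(vc$alpha, cst$e1 * cst$a1, tolerance = 1e-12)
    expect_equal(vc$beta, cst$e2 * (cst$a1^2 + cst$a2), tolerance = 1e-12)
    # and the sigma matrix itself reproduces Var(S) and Var(pi)
    expect_equal(sum(sigma), cst$a2, tolerance = 1e-12)
    wpi <- i * (n - i) / (n * (n - 1) / 2)
    vpi <- fusim:::spectrum_var_coefs(wpi, sigma)
    expect_equal(vpi$alpha, (n + 1) / (3 * (n - 1)), tolerance = 1e-12)
    expect_equal(vpi$beta, 2 * (n^2 + n + 3) / (9 * n * (n - 1)),
                 tolerance = 1e-12)
  }
})

test_that("Y* matches its frozen value on a singleton-plus-shared toy", {
  aln <- rbind(c("T", "T", "A"), c("T", "T", "A"), c("T", "A", "A"),
               c("A", "A", "A"), c("A", "A", "A"), c("A", "A", "T"))
  s <- site_summary(aln)
  expect_equal(s$S, 3)
  expect_equal(s$eta_S, 1)
  expect_equal(achaz_Y_star(s), 0.4581181282, tolerance = 1e-9)
})

test_that("the neutral null centers D, F*, FS and Y* near zero", {
  n <- 20; theta <- 5
  set.seed(77)
  M <- fusim:::cpp_null_summaries(n, theta, 2000L, 0L, 0, 1, 0, 0, 0)
  st <- fusim:::stats_from_counts(n, M)
  for (s in c("D", "Fstar", "Ystar")) {
    m <- mean(st[, s], na.rm = TRUE)
    expect_lt(abs(m), 0.15)
  }
  # FS is slightly right-skewed under neutrality but close to zero
  expect_lt(abs(mean(st[, "FS"], na.rm = TRUE)), 0.45)
  # normalized statistics should have roughly unit spread
  expect_gt(sd(st[, "D"], na.rm = TRUE), 0.6)
  expect_lt(sd(st[, "D"], na.rm = TRUE), 1.3)
})

test_that("demography moves D and FS in the documented directions", {
  pod <- list(n_alleles = 20, theta_w = rep(3, 8))
  growth <- estimate_distributions(pod, canonical_nonfusion_models()$growth4x,
                                   n_reps = 300, seed = 5)
  decline <- estimate_distributions(pod, canonical_nonfusion_models()$decline0.25x,
                                    n_reps = 300, seed = 6)
  fusion <- estimate_distributions(pod, canonical_fusion_scenarios()$DL9,
                                   n_reps = 300, seed = 7)
  const <- estimate_distributions(pod, single_deme_model("constant", 1e4),
                                  n_reps = 300, seed = 8)
  for (s in c("D", "FS")) {
    expect_lt(mean(growth$values[[s]]), 0)
    expect_gt(mean(decline$values[[s]]), mean(const$values[[s]]))
    expect_gt(mean(fusion$values[[s]]), mean(const$values[[s]]))
    expect_gt(mean(fusion$values[[s]]), mean(growth$values[[s]]))
  }
  expect_gt(mean(fusion$values$D), 0)
})

test_that("profiles average only over defined loci and report exclusions", {
  mono <- matrix("A", 4, 30)
  poly <- toy_split
  prof <- sumstat_profile(list(poly, mono))
  expect_equal(prof$n_defined[["D"]], 1L)
  expect_equal(prof$across_loci[["D"]], tajima_D(site_summary(poly)))
  expect_equal(prof$across_loci[["Hd"]], mean(c(2 / 3, 0)))
  all_mono <- sumstat_profile(list(mono, mono))
  expect_true(all(all_mono$n_defined == 0))
  expect_equal(all_mono$across_loci[["Hd"]], 0)
})
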