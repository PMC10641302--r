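test_that("canonical fusion scenarios span D:L ratios 1, 3, 5, 9", {
  sc <- canonical_fusion_scenarios()
  expect_length(sc, 4)
  expect_equal(vapply(sc, function(s) s$dl_ratio, 0, USE.NAMES = FALSE),
               c(1, 3, 5, 9))
  expect_equal(vapply(sc, function(s) s$t_div, 0, USE.NAMES = FALSE),
               c(20000, 40000, 60000, 100000))
  expect_true(all(vapply(sc, function(s) s$mix, 0) == 0.5))
  expect_true(all(vapply(sc, function(s) s$base_Ne, 0) == 10000))
  expect_true(all(vapply(sc, function(s) s$t_fuse, 0) == 10000))
  expect_equal(sc[[1]]$t_div, 20000)
  expect_equal(sc[[4]]$dl_ratio, (100000 - 10000) / 10000)
})

test_that("canonical non-fusion models follow the plotting order and timings", {
  m <- canonical_nonfusion_models()
  expect_length(m, 10)
  expect_equal(vapply(m, function(x) x$kind, ""),
               c(constant = "constant", growth2x = "growth",
                 growth3x = "growth", growth4x = "growth",
                 bottleneck0.5x = "bottleneck", bottleneck0.33x = "bottleneck",
                 bottleneck0.25x = "bottleneck", decline0.5x = "decline",
                 decline0.33x = "decline", decline0.25x = "decline"))
  expect_equal(m[[1]]$factor, 1)
  expect_equal(m[[5]]$factor, 0.5)
  expect_equal(m[[5]]$t_start, 20000)
  expect_equal(m[[5]]$t_end, 10000)
  expect_equal(m[[8]]$factor, 0.5)
  expect_equal(m[[8]]$t_event, 10000)
  # printed "0.33x"/"0.25x" magnitudes are exact thirds and quarters
  expect_equal(m[["bottleneck0.33x"]]$factor, 1 / 3)
  expect_equal(m[["decline0.25x"]]$factor, 1 / 4)
  expect_equal(vapply(m[2:4], function(x) x$factor, 0, USE.NAMES = FALSE),
               c(2, 3, 4))
})

test_that("canonical compositions partition exactly 800,000 bp", {
  cp <- canonical_compositions()
  expect_length(cp, 9)
  tot <- vapply(cp, function(x)
    as.numeric(x$n_alleles) * x$locus_length * x$n_loci, 0)
  expect_true(all(tot == 800000))
  expect_equal(unclass(cp[["POD-3"]])[1:3],
               list(n_alleles = 10L, locus_length = 8000L, n_loci = 10L))
  expect_equal(unclass(cp[["POD-7"]])[1:3],
               list(n_alleles = 40L, locus_length = 200L, n_loci = 100L))
})

test_that("model invariants are enforced", {
  expect_error(fusion_scenario(10000, t_div = 5000, t_fuse = 10000),
               "t_div > t_fuse")
  expect_error(fusion_scenario(10000, t_div = 20000, t_fuse = 10000, mix = 1.2),
               "mix")
  expect_error(fusion_scenario(1, t_div = 20000, t_fuse = 10000), "base_Ne")
  expect_error(single_deme_model("constant", 10000, factor = 2), "factor")
  expect_error(single_deme_model("growth", 10000, factor = 0.5, t_event = 1e4),
               "growth")
  expect_error(single_deme_model("decline", 10000, factor = 2, t_event = 1e4),
               "decline")
  expect_error(single_deme_model("bottleneck", 10000, factor = 0.5,
                                 t_start = 1e4, t_end = 2e4), "bottleneck")
  expect_error(dataset_composition(11, 100, 10), "even")
  expect_error(dataset_composition(10, -5, 10), "positive")
})

test_that("models survive a JSON round trip", {
  for (m in c(canonical_fusion_scenarios()[2],
              canonical_nonfusion_models()[c(1, 5, 9)])) {
    js <- model_to_json(m)
    expect_equal(model_from_json(js), m)
  }
  f <- tempfile(fileext = ".json")
  model_to_json(canonical_compositions()[["POD-8"]], f)
  expect_equal(model_from_json(f), canonical_compositions()[["POD-8"]])
  unlink(f)
})
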