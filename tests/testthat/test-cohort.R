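test_that("moment-matched positive draws reproduce the target moments", {
  set.seed(61)
  x <- rtnorm_moments(2e5, 1, 0.25)        # truncated-normal path
  expect_true(all(x > 0))
  expect_equal(mean(x), 1, tolerance = 0.01)
  expect_equal(sd(x), 0.25, tolerance = 0.01)
  y <- rtnorm_moments(2e5, 0.55, 0.6164)   # lognormal fallback (cv > 1)
  expect_true(all(y > 0))
  expect_equal(mean(y), 0.55, tolerance = 0.01)
  expect_equal(sd(y), 0.6164, tolerance = 0.02)
  z <- rtnorm_moments(2e5, 1, 0.25, model = "lognormal")
  expect_equal(c(mean(z), sd(z)), c(1, 0.25), tolerance = 0.01)
  expect_error(rtnorm_moments(10, -1, 1), "positive")
})

test_that("generation is deterministic in the seed and respects group sizes", {
  cfg <- small_config(seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(small_config(seed = 10))
  expect_false(identical(a$spots$abundances, c2$spots$abundances))
  s <- a$subjects
  expect_equal(sum(s$group == "AD" & s$phase == "discovery"), 22)
  expect_equal(sum(s$group == "control" & s$phase == "discovery"), 25)
  expect_equal(sum(s$group == "AD" & s$phase == "verification"), 40)
  expect_equal(sum(s$group == "control" & s$phase == "verification"), 38)
})

test_that("APOE carrier fractions and the GSTO1 stratum rule hold", {
  cfg <- cohort_config(n_ad_discovery = 1000, n_co_discovery = 1000,
                       n_ad_verification = 10, n_co_verification = 10,
                       n_spots = 5, planted_effects = list(), seed = 12)
  s <- generate_cohort(cfg)$subjects
  # carrier fractions near 68 % (AD) and 11 % (controls), binomial error
  expect_equal(mean(s$apoe_e4_count[s$group == "AD"] > 0), 42 / 62,
               tolerance = 0.05)
  expect_equal(mean(s$apoe_e4_count[s$group == "control"] > 0), 7 / 63,
               tolerance = 0.04)
  # e4-negative AD patients are homozygous A140 by construction
  expect_true(all(s$gsto1_a140_count[s$group == "AD" & s$apoe_e4_count == 0] == 2))
  expect_true(all(s$gsto1_a140_count + s$gsto1_d140_count == 2))
})

test_that("planted (ratio, d) pairs are recovered at large n per group", {
  # n = 5000/group keeps the Monte-Carlo error of d-hat well below the
  # +/-0.05 recovery band even for the heavy-tailed ApoE3 spot (cv > 1)
  cfg <- cohort_config(n_ad_discovery = 5000, n_co_discovery = 5000,
                       n_ad_verification = 10, n_co_verification = 10,
                       n_spots = 10, missing_rate = 0,
                       planted_effects = list(
                         planted_spot(1L, "MaoB", 1, 1.38, 1.27),
                         planted_spot(2L, "ApoE3", 1, 0.55, 0.73),
                         planted_spot(3L, "Tm1", 1, 1.29, 0.76)),
                       seed = 13)
  co <- generate_cohort(cfg)
  keep <- co$subjects$phase == "discovery"
  ad <- co$subjects$subject_id[keep & co$subjects$group == "AD"]
  ct <- co$subjects$subject_id[keep & co$subjects$group == "control"]
  for (row in 1:3) {
    x <- co$spots$abundances[row, ad]; y <- co$spots$abundances[row, ct]
    target <- cfg$planted_effects[[row]]
    expect_equal(mean(x) / mean(y), target$ad_control_ratio,
                 tolerance = 0.05 / target$ad_control_ratio)
    d <- cohens_d(x, y)$d
    expect_equal(abs(d), target$effect_size_d,
                 tolerance = 0.05 / target$effect_size_d)
    expect_equal(sign(d), sign(target$ad_control_ratio - 1))
  }
})

test_that("genotype-linked spot means increase strictly with allele count", {
  cfg <- cohort_config(n_ad_discovery = 500, n_co_discovery = 500,
                       n_ad_verification = 10, n_co_verification = 10,
                       n_spots = 6, missing_rate = 0, seed = 14,
                       planted_effects = list(
                         planted_spot(1L, "ApoE4", 1, genotype_linked = "APOE_e4",
                                      background = 0.2),
                         planted_spot(2L, "GSTO1_A140", 1,
                                      genotype_linked = "GSTO1_A140")))
  co <- generate_cohort(cfg)
  for (row in 1:2) {
    cnt <- if (row == 1) co$subjects$apoe_e4_count else co$subjects$gsto1_a140_count
    mm <- tapply(co$spots$abundances[row, ], cnt, mean)
    expect_true(all(diff(mm) > 0))
  }
})

test_that("null spots behave as nulls: unit ratio, uniform p-values, balanced missingness", {
  cfg <- cohort_config(planted_effects = list(), n_spots = 880, seed = 15)
  co <- generate_cohort(cfg)
  st <- spot_stats(co$spots, co$subjects, "pooled")
  expect_equal(mean(st$ratio_ad_co), 1, tolerance = 0.01)
  expect_gt(suppressWarnings(ks.test(st$p_raw, "punif"))$p.value, 0.01)
  # missingness independent of the group
  is_ad <- co$subjects$group == "AD"
  mf_ad <- rowMeans(!is.na(co$spots$abundances[, is_ad]))
  mf_co <- rowMeans(!is.na(co$spots$abundances[, !is_ad]))
  expect_equal(mean(mf_ad), mean(mf_co), tolerance = 0.005)
})

test_that("infeasible configurations are rejected with messages", {
  expect_error(planted_spot(1L, "bad", 1, 1.5, 0), "effect_size_d")
  expect_error(planted_spot(1L, "bad", 1, -2, 1), "positive")
  expect_error(cohort_config(n_ad_discovery = 0), "group sizes")
  expect_error(cohort_config(apoe_freqs = list(AD = c(0.5, 0.5, 0.5),
                                               control = c(1, 0, 0))),
               "summing to 1")
  expect_error(cohort_config(planted_effects = list(
    planted_spot(1L, "a"), planted_spot(1L, "b"))), "unique")
  expect_error(cohort_config(planted_effects = list(planted_spot(2000L, "a"))),
               "1..n_spots")
  expect_error(cohort_config(missing_rate = 1.2), "missing_rate")
  # e4-negative AD stratum is forced to A140 frequency 1
  cfg <- cohort_config(gsto1_a140_allele_freq = c(ad_e4neg = 0.5, ad_e4pos = 0.32,
                                                  co_e4neg = 0.38, co_e4pos = 0.38))
  expect_equal(unname(cfg$gsto1_a140_allele_freq["ad_e4neg"]), 1.0)
})

test_that("dilution series: noiseless proportionality, r >= 0.99 at 3 % CV", {
  ds0 <- generate_dilution_series(6, cv = 0, seed = 1)
  expect_equal(pearson_r(ds0$platelet_count, ds0$erk2_signal), 1.0)
  expect_equal(ds0$platelet_count[1] / ds0$platelet_count[6], 32) # two-fold ladder
  rs <- vapply(1:40, function(s) {
    ds <- generate_dilution_series(6, cv = 0.03, seed = s)
    pearson_r(ds$platelet_count, ds$erk2_signal)
  }, 1)
  expect_gte(median(rs), 0.99)
  expect_error(generate_dilution_series(2, cv = 0.03), "at least 3")
  expect_error(generate_dilution_series(6, cv = -0.1), "non-negative")
})
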