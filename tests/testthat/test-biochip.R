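four_pl <- function(x, lower, upper, midpoint, slope)
  lower + (upper - lower) / (1 + (x / midpoint)^(-slope))

test_that("4PL calibration: exact round trip, noisy bias, monotonicity guard", {
  conc <- c(0.05, 0.1, 0.5, 1, 5, 10, 50)
  sig <- four_pl(conc, lower = 50, upper = 4000, midpoint = 2, slope = 1.3)
  cal <- fit_calibration(conc, sig, analyte = "MaoB")
  expect_equal(cal$parameters$lower, 50, tolerance = 1e-5)
  expect_equal(cal$parameters$upper, 4000, tolerance = 1e-5)
  expect_equal(cal$parameters$midpoint, 2, tolerance = 1e-5)
  expect_equal(cal$parameters$slope, 1.3, tolerance = 1e-5)
  # 5 % signal noise: bias of the median parameter estimate below 5 %
  set.seed(81)
  est <- replicate(60, {
    noisy <- sig * exp(rnorm(length(sig), 0, 0.05))
    p <- fit_calibration(conc, noisy)$parameters
    c(p$upper, p$midpoint, p$slope)
  })
  bias <- abs(apply(est, 1L, median) / c(4000, 2, 1.3) - 1)
  expect_lt(max(bias), 0.05)
  expect_error(fit_calibration(conc, rev(sig)), "monotone")
  expect_error(fit_calibration(conc[1:4], sig[1:4]), "at least 5")
})

test_that("quantification inverts the curve in range and flags beyond the asymptotes", {
  conc <- c(0.05, 0.1, 0.5, 1, 5, 10, 50)
  cal <- fit_calibration(conc, four_pl(conc, 50, 4000, 2, 1.3))
  x <- c(0.1, 0.7, 3, 20)
  q <- quantify(predict(cal, x), cal)
  expect_equal(q$concentration, x, tolerance = 1e-6)
  expect_true(all(q$status == "ok"))
  # at/above the upper asymptote: flagged, never extrapolated
  q2 <- quantify(c(4000, 4500, 10), cal)
  expect_true(all(is.na(q2$concentration)))
  expect_equal(q2$status, c("above_range", "above_range", "below_range"))
  # plasma analyte bookkeeping: dilution factor multiplies the concentration
  q3 <- quantify(predict(cal, 0.7), cal, dilution_factor = 10)
  expect_equal(q3$concentration, 7, tolerance = 1e-6)
})

test_that("ERK2 normalization cancels per-sample loading factors exactly", {
  set.seed(82)
  n <- 30
  panel <- data.frame(sample_id = sprintf("S%02d", 1:n),
                      maob = runif(n, 0.5, 2), tm1 = runif(n, 0.5, 2),
                      gsto1_a140 = runif(n), erk2 = 1,
                      apoe4 = runif(n), pan_apoe = runif(n, 0.8, 1.2),
                      ppp_dilution_factor = 10)
  load <- runif(n, 0.3, 3)  # arbitrary per-sample loading
  scaled <- panel
  for (cc in c("maob", "tm1", "gsto1_a140", "erk2")) scaled[[cc]] <- panel[[cc]] * load
  norm0 <- erk2_normalize(panel)
  norm1 <- erk2_normalize(scaled)
  expect_equal(norm1$maob_norm, norm0$maob_norm, tolerance = 1e-12)
  expect_equal(norm1$tm1_norm, norm0$tm1_norm, tolerance = 1e-12)
  # constant ERK2: normalization is a global rescale, AUC untouched
  grp <- rep(c("AD", "control"), n / 2)
  expect_equal(roc_auc(norm0$maob_norm, grp), roc_auc(panel$maob, grp))
  # panApoE option normalizes the plasmatic analyte by panApoE
  normp <- erk2_normalize(panel, apoe_norm = "pan_apoe")
  expect_equal(normp$apoe4_norm, panel$apoe4 / panel$pan_apoe)
  bad <- panel; bad$erk2[1] <- 0
  expect_error(erk2_normalize(bad), "positive")
})

test_that("normalization rescues marker significance under platelet-count variation", {
  # platelet CV ~36 % obscures the MaoB effect in raw concentrations
  improved <- vapply(1:20, function(s) {
    co <- generate_cohort(small_config(seed = s))
    grp <- co$subjects$group
    norm <- erk2_normalize(co$panel)
    p_raw <- mann_whitney(co$panel$maob[grp == "AD"],
                          co$panel$maob[grp == "control"])$p_value
    p_norm <- mann_whitney(norm$maob_norm[grp == "AD"],
                           norm$maob_norm[grp == "control"])$p_value
    p_norm < p_raw
  }, TRUE)
  expect_gte(mean(improved), 0.9)
})

test_that("genotype calls match generator truth (APOE ~100 %, GSTO1 >= 98 %)", {
  concs <- vapply(1:6, function(s) {
    co <- generate_cohort(small_config(seed = 100 + s))
    norm <- erk2_normalize(co$panel, apoe_norm = "pan_apoe")
    g <- call_genotypes(norm)
    c(concordance(g$apoe_e4_count, co$subjects$apoe_e4_count)$concordance,
      concordance(g$gsto1_a140_count, co$subjects$gsto1_a140_count)$concordance)
  }, c(apoe = 1, gsto1 = 1))
  expect_gte(mean(concs["apoe", ]), 0.99)
  expect_gte(mean(concs["gsto1", ]), 0.98)
})

test_that("allele calling: zero signal, fixed thresholds, guard-band no-calls", {
  expect_equal(call_alleles(c(0, 0.01), thresholds = c(0.3, 0.75))[1:2],
               c(0L, 0L))
  x <- c(0.05, 0.5, 1.1, 0.74)  # last value inside the guard band
  calls <- call_alleles(x, thresholds = c(0.3, 0.75), guard_band = 0.05)
  expect_equal(calls[1:3], c(0L, 1L, 2L))
  expect_true(is.na(calls[4]))
  # no-calls are excluded from the concordance denominator
  cc <- concordance(calls, c(0L, 1L, 2L, 2L), ids = letters[1:4])
  expect_equal(cc$concordance, 1)
  expect_equal(cc$n_nocall, 1)
  expect_error(call_alleles(x, thresholds = c(0.8, 0.3)), "increasing")
})

test_that("concordance arithmetic and chance agreement", {
  expect_equal(concordance(rep(1L, 10), rep(1L, 10))$concordance, 1)
  calls <- c(rep(0:2, 34))  # 102 calls
  truth <- calls; truth[1] <- 2L
  cc <- concordance(calls, truth)
  expect_equal(cc$concordance, 101 / 102)
  expect_equal(cc$discordant, 1)
  # random calls against a 3-category truth: agreement near sum(p_i q_i)
  set.seed(84)
  p <- c(0.2, 0.5, 0.3); q <- c(0.6, 0.3, 0.1)
  r <- concordance(sample(0:2, 2e4, TRUE, p), sample(0:2, 2e4, TRUE, q))
  expect_equal(r$concordance, sum(p * q), tolerance = 0.02)
  expect_error(concordance(1:3, 1:4), "equal length")
})
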