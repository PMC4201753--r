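test_that("Mann-Whitney U equals brute-force pair counts, with and without ties", {
  expect_equal(mann_whitney(c(3, 4, 5), c(1, 2))$statistic, 6)
  tied <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$statistic, 4.5)
  expect_gt(tied$p_value, 0.99)

  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(2:60, 1); n2 <- sample(2:60, 1)
    x <- sample(1:8, n1, replace = TRUE)  # heavy ties
    y <- sample(1:8, n2, replace = TRUE)
    expect_equal(mann_whitney(x, y)$statistic, bf_u(x, y))
    # complement identity U(x,y) + U(y,x) = n1 n2
    expect_equal(mann_whitney(x, y)$statistic + mann_whitney(y, x)$statistic,
                 n1 * n2)
  }
})

test_that("exact-path p equals exhaustive permutation p; large-sample path matches wilcox.test", {
  set.seed(21)
  for (i in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, bf_exact_p(x, y),
                 tolerance = 1e-12)
  }
  # tie-corrected normal approximation agrees with stats::wilcox.test
  for (i in 1:10) {
    x <- rnorm(30) + 0.5; y <- rnorm(25)
    ours <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, correct = FALSE,
                                               exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Cohen's d uses the average-SD denominator and is antisymmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  # groups built to have means 1.38 / 1.00 and common SD 0.29921
  base <- c(-1, 0, 1) / sd(c(-1, 0, 1)) * 0.29921
  es <- cohens_d(base + 1.38, base + 1)
  expect_equal(es$d, 1.27, tolerance = 1e-3)
  x <- rnorm(20); y <- rnorm(20, 1)
  expect_equal(cohens_d(x, y)$d, -cohens_d(y, x)$d)
  # exact formula on arbitrary data
  expect_equal(cohens_d(x, y)$d,
               (mean(x) - mean(y)) / ((sd(x) + sd(y)) / 2))
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("KS normality pre-check rejects uniform, retains normal, flags estimation", {
  set.seed(5)
  rejected <- replicate(20, ks_normality(runif(1000))$p_value < 0.05)
  expect_gte(mean(rejected), 0.95)
  kept <- replicate(20, ks_normality(rnorm(500))$p_value >= 0.05)
  expect_gte(mean(kept), 0.9)
  expect_true(ks_normality(rnorm(100))$parameters_estimated)
  expect_error(ks_normality(rep(1, 10)), "constant")
  # Lilliefors variant agrees in direction with the conservative default
  skip_if_not_installed("nortest")
  x <- runif(300)
  expect_lt(ks_normality(x, method = "lilliefors")$p_value, 0.05)
})

test_that("p-value adjustment: Holm fixture, dominance, family size m, idempotence", {
  expect_equal(adjust_pvalues(0.04, m = 1), 0.04)
  # hand-applied Holm step-down over m = 3
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04), m = 3),
               c(0.03, 0.04, 0.04))
  set.seed(3)
  p <- runif(20)
  for (meth in c("holm", "bonferroni", "hochberg", "BH")) {
    adj <- adjust_pvalues(p, m = 25, method = meth)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= 0))  # order-preserving
  }
  # adjusting against a larger family (4 candidates over 890 spots)
  expect_equal(adjust_pvalues(1e-5, m = 890), 1e-5 * 890, tolerance = 1e-12)
  # re-adjustment never undoes an adjustment
  adj1 <- adjust_pvalues(c(0.001, 0.2, 0.9), m = 3)
  expect_true(all(adjust_pvalues(adj1, m = 3) >= adj1))
  expect_error(adjust_pvalues(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_pvalues(c(0.1, 0.2), m = 1), "family size")
})

test_that("chi-square continuity correction touches only empty cells", {
  expect_equal(chi_square_cc(matrix(10, 2, 2))$statistic, 0)
  # statistic equals Pearson formula on the corrected table [[12, 0.5], [5, 7]]
  res <- chi_square_cc(matrix(c(12, 5, 0, 7), 2))
  ref <- suppressWarnings(stats::chisq.test(matrix(c(12, 5, 0.5, 7), 2),
                                            correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  # without zeros the correction is inactive
  tab <- matrix(c(20, 11, 7, 25), 2)
  expect_equal(chi_square_cc(tab)$statistic,
               unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic))
  # invariant under row/column permutation
  expect_equal(chi_square_cc(tab[2:1, ])$statistic,
               chi_square_cc(tab[, 2:1])$statistic)
  # all-cell variant
  expect_equal(chi_square_cc(tab, correct_all = TRUE)$statistic,
               unname(suppressWarnings(stats::chisq.test(tab + 0.5, correct = FALSE))$statistic))
  expect_error(chi_square_cc(matrix(c(0, 0, 1, 2), 2)), "all-zero")
})

test_that("Pearson correlation matches the covariance formula and handles errors", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  y <- c(2, 1, 5, 4, 8)
  expect_equal(pearson_r(x, y),
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), "constant")
  expect_error(pearson_r(1:4, 1:3), "equal length")
})
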