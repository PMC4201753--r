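#' plateletAD: platelet-proteome biomarker screening and diagnostic scores
#'
#' Implements a two-stage 2D-DIGE discovery/verification screen for
#' differentially abundant platelet protein spots, composite diagnostic sum
#' scores (models 0--6) with an APOE epsilon-4 genotype branch, Firth-penalized
#' logistic regression, nonparametric ROC evaluation, and multiplex biochip
#' processing (calibration, loading-control normalization, proteomic
#' genotyping), together with a synthetic cohort generator that mirrors the
#' statistical structure of the underlying study.
#'
#' @keywords internal
"_PACKAGE"

#' Mann-Whitney U test
#'
#' Rank-sum test of two independent samples. The U statistic counts pairs
#' `(x_i, y_j)` with `x_i > y_j`, ties contributing 1/2. For combined sample
#' sizes up to `exact_max` the two-sided p-value is computed by exhaustive
#' enumeration of all group assignments of the pooled values; above that, a
#' tie-corrected normal approximation is used.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param exact_max combined sample size at or below which the exact
#'   enumeration path is taken (default 12).
#' @return A list of class `"ad_test"` with elements `statistic` (U for `x`
#'   over `y`), `p_value`, `method`, `n1`, `n2`.
#' @examples
#' mann_whitney(c(3, 4, 5), c(1, 2))$statistic  # 6: all pairs favour x
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) { x <- x[!is.na(x)]; y <- y[!is.na(y)] }
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty after NA removal")
  n1 <- as.numeric(length(x)); n2 <- as.numeric(length(y)); n <- n1 + n2
  u <- .u_stat(x, y)
  if (n <= exact_max) {
    pooled <- c(x, y)
    idx <- utils::combn(n, n1)
    mu <- n1 * n2 / 2
    dev <- abs(u - mu)
    us <- apply(idx, 2L, function(i) .u_stat(pooled[i], pooled[-i]))
    p <- mean(abs(us - mu) >= dev - 1e-12)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu) / sqrt(sig2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  structure(list(statistic = u, p_value = p, method = method, n1 = n1, n2 = n2),
            class = "ad_test")
}

# U for x over y via midranks: U = R1 - n1(n1+1)/2
.u_stat <- function(x, y) {
  n1 <- as.numeric(length(x))
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' @export
print.ad_test <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  cat(sprintf("statistic = %.4g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(x) - mean(y)) / ((sd(x) + sd(y)) / 2)`,
#' i.e. the difference scaled by the plain average of the two group standard
#' deviations (not the pooled SD).
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return A list of class `"effect_size"`: `d`, `mean1`, `mean2`, `sd1`, `sd2`.
#' @export
cohens_d <- function(x, y) {
  x <- as.numeric(stats::na.omit(x)); y <- as.numeric(stats::na.omit(y))
  if (length(x) < 2L || length(y) < 2L) stop("each group needs at least 2 values")
  m1 <- mean(x); m2 <- mean(y); s1 <- stats::sd(x); s2 <- stats::sd(y)
  if (s1 + s2 == 0) stop("both groups are constant; effect size undefined")
  structure(list(d = (m1 - m2) / ((s1 + s2) / 2),
                 mean1 = m1, mean2 = m2, sd1 = s1, sd2 = s2),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f  (means %.3f vs %.3f; SDs %.3f, %.3f)\n",
              x$d, x$mean1, x$mean2, x$sd1, x$sd2))
  invisible(x)
}

#' Kolmogorov-Smirnov normality pre-check
#'
#' One-sample KS test against a normal distribution with mean and SD estimated
#' from the sample. Because the parameters are estimated, the classical KS
#' p-value is conservative; `method = "lilliefors"` applies the Lilliefors
#' correction (via the nortest package) instead.
#'
#' @param x numeric vector, `n >= 5`, not constant.
#' @param method `"ks"` (classical, conservative) or `"lilliefors"`.
#' @return `"ad_test"` list; the classical variant carries
#'   `parameters_estimated = TRUE` as a reminder of its conservatism.
#' @export
ks_normality <- function(x, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  x <- as.numeric(stats::na.omit(x))
  if (length(x) < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("sample is constant; normality test undefined")
  if (method == "lilliefors") {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop("method = 'lilliefors' requires the nortest package")
    ht <- nortest::lillie.test(x)
    out <- list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = "Lilliefors (KS, estimated parameters)",
                n1 = length(x), n2 = NA_integer_)
  } else {
    ht <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    out <- list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = "Kolmogorov-Smirnov vs fitted normal (conservative: parameters estimated)",
                n1 = length(x), n2 = NA_integer_,
                parameters_estimated = TRUE)
  }
  structure(out, class = "ad_test")
}

#' Multiple-comparison adjustment over m hypotheses
#'
#' Wrapper around [stats::p.adjust()] that makes the size of the hypothesis
#' family explicit: `m` may exceed `length(p)` (e.g. 4 verified candidates
#' adjusted against the 890 spots of the full matched-spot universe).
#'
#' @param p numeric p-values in \[0, 1\].
#' @param m family size, `m >= length(p)`.
#' @param method adjustment method; Holm step-down by default, or any of
#'   `"bonferroni"`, `"hochberg"`, `"BH"`.
#' @return adjusted p-values, pointwise `>= p`, capped at 1.
#' @export
adjust_pvalues <- function(p, m = length(p),
                           method = c("holm", "bonferroni", "hochberg", "BH")) {
  method <- match.arg(method)
  p <- as.numeric(p)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= length(p)")
  stats::p.adjust(p, method = method, n = m)
}

#' Pearson chi-square with ad-hoc continuity correction
#'
#' Pearson chi-square test of independence on a contingency table after adding
#' 0.5 to empty cells (default) or, with `correct_all = TRUE`, to every cell
#' (Haldane-Anscombe style).
#'
#' @param tab matrix of non-negative counts, at least 2x2.
#' @param correct_all add 0.5 to all cells rather than only empty ones.
#' @return `"ad_test"` list with the chi-square statistic, p-value from the
#'   chi-square distribution with `(r-1)(c-1)` df, and the corrected table as
#'   attribute `"corrected"`.
#' @export
chi_square_cc <- function(tab, correct_all = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has an all-zero row or column")
  ctab <- tab
  if (correct_all) ctab <- ctab + 0.5 else ctab[ctab == 0] <- 0.5
  e <- outer(rowSums(ctab), colSums(ctab)) / sum(ctab)
  stat <- sum((ctab - e)^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  out <- structure(list(statistic = stat,
                        p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                        method = sprintf("Pearson chi-square (0.5 added to %s cells), df = %d",
                                         if (correct_all) "all" else "empty", df),
                        n1 = sum(tab), n2 = NA_integer_),
                   class = "ad_test")
  attr(out, "corrected") <- ctab
  out
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length `>= 3`, neither constant.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input; correlation undefined")
  stats::cor(x, y)
}
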