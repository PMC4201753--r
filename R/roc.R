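#' Nonparametric AUC
#'
#' Area under the empirical ROC curve, computed by the rank (Mann-Whitney)
#' statistic: `AUC = P(score_pos > score_neg) + 0.5 P(tie)`. Higher scores are
#' taken as more disease-like.
#'
#' @param scores numeric scores, one per subject.
#' @param labels group labels; coerced with [as_binary_labels()]. The positive
#'   (diseased) class is `positive`.
#' @param positive value of `labels` identifying the positive class; by
#'   default `"AD"`, `1`, or `TRUE` is detected automatically.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n1 <- as.numeric(sum(y == 1L)); n0 <- as.numeric(sum(y == 0L))
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Coerce group labels to 0/1
#'
#' @param labels factor, character, logical or numeric labels with exactly two
#'   levels present (a single level is allowed only if `positive` is given).
#' @param positive the positive-class value; if `NULL`, `"AD"`, `1`, `TRUE`
#'   or the second factor level is used.
#' @return integer vector of 0 (negative/control) and 1 (positive/case).
#' @export
as_binary_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(as.integer(labels))
  lv <- unique(stats::na.omit(as.character(labels)))
  if (is.null(positive)) {
    positive <- if ("AD" %in% lv) "AD"
    else if (all(lv %in% c("0", "1"))) "1"
    else if (is.factor(labels)) levels(labels)[2L]
    else stop("cannot infer the positive class; supply `positive`")
  }
  positive <- as.character(positive)
  if (!positive %in% lv && length(lv) > 0L)
    stop(sprintf("positive class '%s' not found in labels", positive))
  as.integer(as.character(labels) == positive)
}

#' ROC evaluation: AUC, standard error, confidence interval, cut-off
#'
#' Computes the rank-based AUC, its standard error (Hanley-McNeil by default,
#' DeLong optionally), a normal-approximation confidence interval clipped to
#' \[0, 1\], and the least-squares optimal cut-off with its sensitivity and
#' specificity.
#'
#' @inheritParams roc_auc
#' @param conf_level confidence level (default 0.95).
#' @param se_method `"hanley-mcneil"` or `"delong"`.
#' @return list of class `"roc_result"`: `auc`, `se`, `ci_low`, `ci_high`,
#'   `cutoff`, `sensitivity`, `specificity`, `n_pos`, `n_neg`.
#' @export
roc_eval <- function(scores, labels, positive = NULL, conf_level = 0.95,
                     se_method = c("hanley-mcneil", "delong")) {
  se_method <- match.arg(se_method)
  y <- as_binary_labels(labels, positive)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 subjects per class")
  a <- roc_auc(scores, y, positive = 1L)
  if (se_method == "delong") {
    # placement-value (structural component) variance
    pos <- scores[y == 1L]; neg <- scores[y == 0L]
    v10 <- vapply(pos, function(s) mean(s > neg) + 0.5 * mean(s == neg), 1)
    v01 <- vapply(neg, function(s) mean(pos > s) + 0.5 * mean(pos == s), 1)
    se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  } else {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
                 (n1 * n0))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  co <- best_cutoff(scores, y, positive = 1L)
  structure(list(auc = a, se = se,
                 ci_low = max(0, a - z * se), ci_high = min(1, a + z * se),
                 cutoff = co$cutoff, sensitivity = co$sensitivity,
                 specificity = co$specificity, n_pos = n1, n_neg = n0,
                 se_method = se_method, conf_level = conf_level),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (SE %.3f, %d %% CI %.3f-%.3f; %s)\n",
              x$auc, x$se, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$se_method))
  cat(sprintf("cut-off = %.3f: sensitivity = %.0f %%, specificity = %.0f %%  (n = %d/%d)\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Least-squares optimal cut-off
#'
#' Chooses the threshold minimizing the squared Euclidean distance
#' `(1 - sensitivity)^2 + (1 - specificity)^2` to the ideal ROC corner (0, 1).
#' Candidate thresholds are the midpoints between adjacent distinct scores
#' plus one below and one above the observed range; subjects with
#' `score >= cutoff` are called positive. Ties in the objective are broken
#' toward higher sensitivity.
#'
#' @inheritParams roc_auc
#' @return list with `cutoff`, `sensitivity`, `specificity`, `objective`.
#' @export
best_cutoff <- function(scores, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  if (!any(y == 1L) || !any(y == 0L)) stop("both classes must be present")
  s <- sort(unique(scores))
  cand <- if (length(s) == 1L) c(s - 1, s + 1)
  else c(s[1L] - 1, (s[-1L] + s[-length(s)]) / 2, s[length(s)] + 1)
  best <- NULL
  for (ct in cand) {
    pos <- scores >= ct
    se <- mean(pos[y == 1L])
    sp <- mean(!pos[y == 0L])
    obj <- (1 - se)^2 + (1 - sp)^2
    if (is.null(best) || obj < best$objective - 1e-12 ||
        (abs(obj - best$objective) <= 1e-12 && se > best$sensitivity)) {
      best <- list(cutoff = ct, sensitivity = se, specificity = sp,
                   objective = obj)
    }
  }
  best
}
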