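#' Per-spot differential statistics
#'
#' For every spot of a 2D-DIGE SA matrix, computes on the samples of the
#' requested phase (complete cases per spot): the AD/control ratio of group
#' mean SAs, the Mann-Whitney p-value, the nonparametric AUC, and Cohen's d.
#' Spots matched in 80 % or fewer of all gels are flagged (`low_matched`),
#' never silently dropped.
#'
#' @param spots a `"spot_matrix"` (from [generate_cohort()] or
#'   [read_spot_matrix()]).
#' @param subjects subject table with `subject_id`, `group`, `phase`.
#' @param phase `"discovery"`, `"verification"`, or `"pooled"` (all samples).
#' @param matched_min matched-fraction floor of filter criterion (a)
#'   (default 0.80, strict inequality), assessed on all gels.
#' @return data.frame of class `"spot_stats"`: `spot_id`, `name`,
#'   `ratio_ad_co`, `p_raw`, `auc`, `effect_size`, `matched_fraction`,
#'   `low_matched`, `phase`, `n_ad`, `n_co`.
#' @export
spot_stats <- function(spots, subjects, phase = c("pooled", "discovery", "verification"),
                       matched_min = 0.80) {
  stopifnot(inherits(spots, "spot_matrix"))
  phase <- match.arg(phase)
  keep <- if (phase == "pooled") rep(TRUE, nrow(subjects)) else subjects$phase == phase
  sub <- subjects[keep, , drop = FALSE]
  m <- spots$abundances[, sub$subject_id, drop = FALSE]
  is_ad <- sub$group == "AD"
  if (!any(is_ad) || !all(c(TRUE, FALSE) %in% unique(is_ad)))
    stop("phase '", phase, "' must contain both groups")

  stats_one <- function(v) {
    x <- v[is_ad]; y <- v[!is_ad]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
      return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    ratio <- mean(x) / mean(y)
    p <- mann_whitney(x, y)$p_value
    a <- roc_auc(c(x, y), rep(c(1L, 0L), c(length(x), length(y))), positive = 1L)
    d <- tryCatch(cohens_d(x, y)$d, error = function(e) NA_real_)
    c(ratio, p, a, d)
  }
  res <- t(apply(m, 1L, stats_one))
  out <- data.frame(spot_id = spots$spot_info$spot_id,
                    name = spots$spot_info$name,
                    ratio_ad_co = res[, 1L], p_raw = res[, 2L],
                    auc = res[, 3L], effect_size = res[, 4L],
                    matched_fraction = spots$matched_fraction,
                    low_matched = !(spots$matched_fraction > matched_min),
                    phase = phase, n_ad = sum(is_ad), n_co = sum(!is_ad),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("spot_stats", "data.frame")
  out
}

#' Discovery-phase candidate filter
#'
#' Applies filter criteria (a)-(c) of the two-stage screen to
#' discovery-phase [spot_stats()]: (a) matched in more than `matched_min` of
#' all gels, (b) AD/control SA ratio greater than `ratio_hi` or smaller than
#' `ratio_lo` (strict inequalities), (c) unadjusted p below `alpha`.
#' Candidates are returned ordered by ascending p-value.
#'
#' @param stats discovery-phase [spot_stats()].
#' @param ratio_hi,ratio_lo ratio gates (defaults 1.20 / 0.80).
#' @param alpha significance level (default 0.05).
#' @param matched_min matched-fraction floor (default 0.80).
#' @param verbose log counts in/out per criterion.
#' @return subset of `stats` (the candidate list), ordered by `p_raw`.
#' @export
discovery_filter <- function(stats, ratio_hi = 1.20, ratio_lo = 0.80,
                             alpha = 0.05, matched_min = 0.80,
                             verbose = FALSE) {
  ok_a <- stats$matched_fraction > matched_min
  ok_b <- !is.na(stats$ratio_ad_co) &
    (stats$ratio_ad_co > ratio_hi | stats$ratio_ad_co < ratio_lo)
  ok_c <- !is.na(stats$p_raw) & stats$p_raw < alpha
  if (verbose) {
    message(sprintf("criterion (a) matched > %.0f %%: %d of %d spots",
                    100 * matched_min, sum(ok_a), nrow(stats)))
    message(sprintf("criterion (b) ratio gates (%.2f/%.2f): %d remain",
                    ratio_lo, ratio_hi, sum(ok_a & ok_b)))
    message(sprintf("criterion (c) p < %.2f: %d candidates",
                    alpha, sum(ok_a & ok_b & ok_c)))
  }
  out <- stats[ok_a & ok_b & ok_c, , drop = FALSE]
  out[order(out$p_raw), , drop = FALSE]
}

#' Verification and whole-cohort confirmation
#'
#' Criteria (d) and (e) of the screen: verification-phase p-values of the
#' discovery candidates are adjusted over the number of candidates; pooled
#' (whole-collective) p-values are adjusted over the full matched-spot
#' universe (`m_pooled`, 890 in the default configuration). Candidates
#' passing both adjusted gates at `alpha` are confirmed.
#'
#' @param candidates output of [discovery_filter()].
#' @param verification_stats,pooled_stats [spot_stats()] of the verification
#'   phase and of the pooled cohort.
#' @param alpha significance level (default 0.05).
#' @param m_pooled adjustment universe for criterion (e); defaults to the
#'   number of spots in `pooled_stats`.
#' @param method p-adjustment method (see [adjust_pvalues()]).
#' @return data.frame with per-candidate discovery/verification/pooled
#'   statistics, the adjusted p-values `p_adj_verification`, `p_adj_pooled`,
#'   and logical `confirmed`; confirmed candidates first, by verification p.
#' @export
verification_confirm <- function(candidates, verification_stats, pooled_stats,
                                 alpha = 0.05, m_pooled = nrow(pooled_stats),
                                 method = "holm") {
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$p_adj_verification <- out$p_adj_pooled <- numeric(0)
    out$confirmed <- logical(0)
    return(out)
  }
  iv <- match(candidates$spot_id, verification_stats$spot_id)
  ip <- match(candidates$spot_id, pooled_stats$spot_id)
  if (anyNA(iv)) stop("candidate spot(s) absent from verification stats: ",
                      paste(candidates$spot_id[is.na(iv)], collapse = ", "))
  if (anyNA(ip)) stop("candidate spot(s) absent from pooled stats: ",
                      paste(candidates$spot_id[is.na(ip)], collapse = ", "))
  p_ver <- verification_stats$p_raw[iv]
  p_all <- pooled_stats$p_raw[ip]
  adj_ver <- adjust_pvalues(p_ver, m = nrow(candidates), method = method)
  adj_all <- adjust_pvalues(p_all, m = m_pooled, method = method)
  out <- data.frame(spot_id = candidates$spot_id, name = candidates$name,
                    ratio_discovery = candidates$ratio_ad_co,
                    p_discovery = candidates$p_raw,
                    ratio_verification = verification_stats$ratio_ad_co[iv],
                    p_verification = p_ver,
                    p_adj_verification = adj_ver,
                    ratio_pooled = pooled_stats$ratio_ad_co[ip],
                    p_pooled = p_all, p_adj_pooled = adj_all,
                    auc_pooled = pooled_stats$auc[ip],
                    effect_size_pooled = pooled_stats$effect_size[ip],
                    confirmed = adj_ver < alpha & adj_all < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$confirmed, out$p_verification), , drop = FALSE]
}

#' Run the full two-stage screen
#'
#' Convenience wrapper: discovery-phase statistics and filter (criteria
#' (a)-(c)), then verification/whole-cohort confirmation ((d), (e)).
#'
#' @param spots,subjects as in [spot_stats()].
#' @param alpha,ratio_hi,ratio_lo,matched_min thresholds of criteria (a)-(e).
#' @param m_pooled criterion-(e) adjustment universe (default: all spots).
#' @param method p-adjustment method.
#' @param verbose log filter counts.
#' @return list: `discovery_stats`, `candidates`, `confirmed` (the
#'   [verification_confirm()] table), `final` (confirmed subset).
#' @export
run_screen <- function(spots, subjects, alpha = 0.05, ratio_hi = 1.20,
                       ratio_lo = 0.80, matched_min = 0.80,
                       m_pooled = NULL, method = "holm", verbose = FALSE) {
  disc <- spot_stats(spots, subjects, "discovery", matched_min = matched_min)
  ver <- spot_stats(spots, subjects, "verification", matched_min = matched_min)
  pool <- spot_stats(spots, subjects, "pooled", matched_min = matched_min)
  cand <- discovery_filter(disc, ratio_hi = ratio_hi, ratio_lo = ratio_lo,
                           alpha = alpha, matched_min = matched_min,
                           verbose = verbose)
  if (is.null(m_pooled)) m_pooled <- nrow(pool)
  conf <- verification_confirm(cand, ver, pool, alpha = alpha,
                               m_pooled = m_pooled, method = method)
  if (verbose)
    message(sprintf("confirmed %d of %d candidates (of %d spots)",
                    sum(conf$confirmed), nrow(cand), nrow(pool)))
  list(discovery_stats = disc, verification_stats = ver, pooled_stats = pool,
       candidates = cand, confirmed = conf,
       final = conf[conf$confirmed, , drop = FALSE])
}
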