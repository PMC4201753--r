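#' Fit a four-parameter-logistic calibration curve
#'
#' Least-squares fit of the standard immunoassay 4PL model
#' `signal = lower + (upper - lower) / (1 + (conc / midpoint)^(-slope))`
#' to calibrator points, via [minpack.lm::nlsLM()]. The calibrator series
#' must be monotone increasing in signal.
#'
#' @param concentration,signal calibrator concentrations (>= 5 points
#'   spanning the range) and measured signals.
#' @param analyte optional analyte label.
#' @return list of class `"calibration_curve"`: `parameters` (`lower`,
#'   `upper`, `midpoint`, `slope`), `range` (calibrator concentration range),
#'   `residuals`, `analyte`.
#' @export
fit_calibration <- function(concentration, signal, analyte = NULL) {
  if (length(concentration) != length(signal)) stop("lengths differ")
  if (length(concentration) < 5L) stop("need at least 5 calibrator points")
  if (any(concentration < 0)) stop("concentrations must be non-negative")
  o <- order(concentration)
  concentration <- concentration[o]; signal <- signal[o]
  if (stats::cor(concentration, signal, method = "spearman") <= 0)
    stop("calibrator series is not monotone increasing; cannot fit a 4PL curve")
  lo0 <- min(signal); hi0 <- max(signal)
  mid0 <- stats::approx(signal, concentration, xout = (lo0 + hi0) / 2,
                        ties = mean)$y
  if (!is.finite(mid0) || mid0 <= 0) mid0 <- stats::median(concentration[concentration > 0])
  df <- data.frame(x = concentration, y = signal)
  fit <- minpack.lm::nlsLM(
    y ~ lower + (upper - lower) / (1 + (x / midpoint)^(-slope)),
    data = df,
    start = list(lower = lo0, upper = hi0 * 1.05, midpoint = mid0, slope = 1),
    lower = c(-Inf, -Inf, 1e-12, 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  if (p[["upper"]] <= p[["lower"]]) stop("degenerate fit: upper <= lower asymptote")
  structure(list(parameters = as.list(p),
                 range = range(concentration[concentration > 0]),
                 residuals = stats::resid(fit), analyte = analyte),
            class = "calibration_curve")
}

#' Predict the signal of a calibration curve
#'
#' @param object a `"calibration_curve"`.
#' @param concentration concentrations to evaluate.
#' @param ... unused.
#' @return predicted signals.
#' @export
predict.calibration_curve <- function(object, concentration, ...) {
  p <- object$parameters
  p$lower + (p$upper - p$lower) / (1 + (concentration / p$midpoint)^(-p$slope))
}

#' @export
print.calibration_curve <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("4PL calibration curve%s\n",
              if (is.null(x$analyte)) "" else paste0(" [", x$analyte, "]")))
  cat(sprintf("  lower %.4g, upper %.4g, midpoint %.4g, slope %.4g\n",
              p$lower, p$upper, p$midpoint, p$slope))
  cat(sprintf("  valid range %.4g - %.4g, residual SD %.3g\n",
              x$range[1], x$range[2], stats::sd(x$residuals)))
  invisible(x)
}

#' Quantify analyte concentrations from signals
#'
#' Inverts a fitted 4PL calibration curve. Signals at or beyond the
#' asymptotes, or mapping outside the calibrated concentration range, are
#' flagged out-of-range and returned as `NA` rather than extrapolated.
#' Plasmatic analytes measured in diluted platelet-poor plasma are corrected
#' by `dilution_factor`.
#'
#' @param signal measured signals.
#' @param curve a `"calibration_curve"`.
#' @param dilution_factor multiplies the interpolated concentration
#'   (default 1; the PPP dilution factor for plasma analytes).
#' @return data.frame: `concentration` (NA when out of range) and `status`
#'   (`"ok"`, `"below_range"`, `"above_range"`).
#' @export
quantify <- function(signal, curve, dilution_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  p <- curve$parameters
  status <- rep("ok", length(signal))
  conc <- rep(NA_real_, length(signal))
  margin <- (p$upper - p$lower) * 1e-9
  below <- signal <= p$lower + margin
  above <- signal >= p$upper - margin
  status[below] <- "below_range"
  status[above] <- "above_range"
  ok <- !below & !above
  # inverse 4PL: c = midpoint * ((y - lower)/(upper - y))^(1/slope)
  conc[ok] <- p$midpoint *
    ((signal[ok] - p$lower) / (p$upper - signal[ok]))^(1 / p$slope)
  oor_lo <- ok & !is.na(conc) & conc < curve$range[1L]
  oor_hi <- ok & !is.na(conc) & conc > curve$range[2L]
  status[oor_lo] <- "below_range"
  status[oor_hi] <- "above_range"
  conc[oor_lo | oor_hi] <- NA_real_
  data.frame(concentration = conc * dilution_factor, status = status,
             stringsAsFactors = FALSE)
}

#' ERK2 loading-control normalization
#'
#' Divides each cellular analyte concentration by the sample's ERK2
#' concentration, cancelling per-sample platelet-number (loading) variation
#' in one step. The plasmatic ApoE4 analyte is normalized by panApoE when
#' `apoe_norm = "pan_apoe"` (the default normalizes it by ERK2 as well).
#'
#' @param panel biochip panel data.frame with columns `erk2` and the
#'   analytes in `cellular`.
#' @param cellular analyte columns to normalize by ERK2.
#' @param apoe_norm `"erk2"` or `"pan_apoe"`: denominator for `apoe4`.
#' @return `panel` with added `<analyte>_norm` columns.
#' @export
erk2_normalize <- function(panel,
                           cellular = c("maob", "tm1", "gsto1_a140"),
                           apoe_norm = c("erk2", "pan_apoe")) {
  apoe_norm <- match.arg(apoe_norm)
  if (!"erk2" %in% names(panel)) stop("panel lacks an 'erk2' column")
  if (any(is.na(panel$erk2)) || any(panel$erk2 <= 0))
    stop("ERK2 concentrations must be present and positive for normalization")
  for (a in intersect(cellular, names(panel)))
    panel[[paste0(a, "_norm")]] <- panel[[a]] / panel$erk2
  if ("apoe4" %in% names(panel)) {
    denom <- if (apoe_norm == "pan_apoe") {
      if (!"pan_apoe" %in% names(panel)) stop("panel lacks 'pan_apoe'")
      panel$pan_apoe
    } else panel$erk2
    panel$apoe4_norm <- panel$apoe4 / denom
  }
  panel
}

#' Proteomic genotype calling
#'
#' Converts a normalized isoform concentration into an allele count 0/1/2 by
#' a two-threshold rule. Thresholds are either supplied (`c(t01, t12)`) or
#' learned by a 1-D 3-cluster partition (k-means on the calibration batch,
#' thresholds at the midpoints between sorted cluster centres). Values
#' inside a guard band around a threshold are returned as `NA` (no-call)
#' rather than forced.
#'
#' @param x normalized isoform concentrations.
#' @param thresholds numeric length-2 `c(t01, t12)`, or `NULL` to learn them.
#' @param guard_band absolute half-width of the no-call band around each
#'   threshold (same units as `x`; default 0.05).
#' @return integer allele counts with `NA` for no-calls; learned thresholds
#'   attached as attribute `"thresholds"`.
#' @export
call_alleles <- function(x, thresholds = NULL, guard_band = 0.05) {
  if (is.null(thresholds)) {
    ux <- stats::na.omit(x)
    if (length(unique(ux)) < 3L) stop("too few distinct values to learn 3 clusters")
    km <- stats::kmeans(ux, centers = stats::quantile(ux, c(0.1, 0.5, 0.9)),
                        iter.max = 100L)
    ctr <- sort(km$centers[, 1L])
    thresholds <- c((ctr[1L] + ctr[2L]) / 2, (ctr[2L] + ctr[3L]) / 2)
  }
  if (length(thresholds) != 2L || thresholds[1L] >= thresholds[2L])
    stop("thresholds must be two increasing values")
  calls <- ifelse(x < thresholds[1L], 0L, ifelse(x < thresholds[2L], 1L, 2L))
  nocall <- abs(x - thresholds[1L]) < guard_band |
    abs(x - thresholds[2L]) < guard_band
  calls[nocall] <- NA_integer_
  structure(as.integer(calls), thresholds = thresholds)
}

#' Genotype a biochip panel
#'
#' Calls APOE e4 and GSTO1*A140 allele counts from the normalized isoform
#' concentrations of a biochip panel ([erk2_normalize()] output). The D140
#' count is the rs4925 complement `2 - A140`.
#'
#' @param panel normalized panel (columns `apoe4_norm`, `gsto1_a140_norm`).
#' @param apoe_thresholds,gsto1_thresholds fixed thresholds (length-2) or
#'   `NULL` to learn them per analyte ([call_alleles()]).
#' @param guard_band no-call half-width passed to [call_alleles()].
#' @return data.frame: `sample_id`, `apoe_e4_count`, `gsto1_a140_count`,
#'   `gsto1_d140_count` (with `NA` for no-calls).
#' @export
call_genotypes <- function(panel, apoe_thresholds = NULL,
                           gsto1_thresholds = NULL, guard_band = 0.05) {
  need <- c("apoe4_norm", "gsto1_a140_norm")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel lacks normalized column(s): ",
                         paste(miss, collapse = ", "),
                         " (run erk2_normalize() first)")
  e4 <- call_alleles(panel$apoe4_norm, apoe_thresholds, guard_band)
  a140 <- call_alleles(panel$gsto1_a140_norm, gsto1_thresholds, guard_band)
  data.frame(sample_id = panel$sample_id,
             apoe_e4_count = as.integer(e4),
             gsto1_a140_count = as.integer(a140),
             gsto1_d140_count = 2L - as.integer(a140),
             stringsAsFactors = FALSE)
}

#' Genotype concordance
#'
#' Fraction of exact allele-count matches between biochip calls and reference
#' genotypes, computed over called samples only (no-calls are excluded from
#' the denominator and reported separately).
#'
#' @param calls,truth integer allele counts; `calls` may contain `NA`
#'   (no-call).
#' @param ids sample identifiers (used to report discordant samples).
#' @return list: `concordance`, `n_called`, `n_nocall`, `discordant` (ids).
#' @export
concordance <- function(calls, truth, ids = seq_along(calls)) {
  if (length(calls) != length(truth) || length(calls) != length(ids))
    stop("calls, truth and ids must have equal length")
  called <- !is.na(calls)
  agree <- calls[called] == truth[called]
  list(concordance = if (any(called)) mean(agree) else NA_real_,
       n_called = sum(called), n_nocall = sum(!called),
       discordant = ids[called][!agree])
}
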