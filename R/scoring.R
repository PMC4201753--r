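#' Composite diagnostic score models 0--6
#'
#' Constructs the specification of one of the seven composite sum-score
#' models combining platelet 2D-DIGE standardized abundances (SA), APOE
#' epsilon-4 allele counts, and (models 5/6) a GSTO1 term that branches on
#' epsilon-4 carrier status:
#'
#' * **0** -- APOE e4 allele count alone
#' * **1** -- MaoB SA alone
#' * **2** -- MaoB SA + e4 count
#' * **3** -- MaoB SA + Tm1 SA + e4 count
#' * **4** -- model 3 + GSTO1*A140 SA
#' * **5** -- model 3 + branch: A140 SA if e4-negative (5a), D140 SA if
#'   e4-positive (5b)
#' * **6** -- biochip format: mean-scaled ERK2-normalized MaoB and Tm1
#'   concentrations + e4 count + branch on allele counts, weighted 0.6
#'   (A140, 6a) or 0.9 (D140, 6b)
#'
#' @param model_id integer 0--6.
#' @param weights model-6 allele-count weights, `c(a140 = 0.6, d140 = 0.9)`.
#' @return list of class `"score_model"` with `model_id`, `components`
#'   (required marker columns), `split_rule` (or `NULL`), `weights`.
#' @export
score_model <- function(model_id, weights = c(a140 = 0.6, d140 = 0.9)) {
  if (!model_id %in% 0:6) stop("model_id must be one of 0, 1, ..., 6")
  if (any(weights <= 0)) stop("weights must be positive")
  components <- switch(as.character(model_id),
    "0" = "apoe_e4_count",
    "1" = "maob_sa",
    "2" = c("maob_sa", "apoe_e4_count"),
    "3" = c("maob_sa", "tm1_sa", "apoe_e4_count"),
    "4" = c("maob_sa", "tm1_sa", "apoe_e4_count", "gsto1_a140_sa"),
    "5" = c("maob_sa", "tm1_sa", "apoe_e4_count",
            "gsto1_a140_sa", "gsto1_d140_sa"),
    "6" = c("maob_norm", "tm1_norm", "apoe_e4_count",
            "gsto1_a140_count", "gsto1_d140_count"))
  split_rule <- if (model_id == 5) {
    list(branch = "apoe_e4_count",
         if_negative = "gsto1_a140_sa", if_positive = "gsto1_d140_sa")
  } else if (model_id == 6) {
    list(branch = "apoe_e4_count",
         if_negative = "gsto1_a140_count", if_positive = "gsto1_d140_count")
  }
  structure(list(model_id = model_id, components = components,
                 split_rule = split_rule,
                 weights = if (model_id == 6) weights),
            class = "score_model")
}

#' Compute composite scores for a marker table
#'
#' Applies a [score_model()] to a per-subject marker table. Expected columns
#' (only those the model uses are required): `maob_sa`, `tm1_sa`,
#' `gsto1_a140_sa`, `gsto1_d140_sa` (2D-DIGE SAs), `apoe_e4_count`,
#' `gsto1_a140_count`, `gsto1_d140_count` (allele counts), and for model 6
#' `maob_norm`, `tm1_norm` (ERK2-normalized biochip concentrations). Model 6
#' divides the normalized concentrations by their average over `norm_group`
#' (by default all rows of the table, i.e. the analyzed batch) to obtain
#' relative values comparable to 2D-DIGE SAs.
#'
#' @param markers data.frame, one row per subject.
#' @param model a [score_model()] or an integer 0--6.
#' @param norm_group optional factor splitting the model-6 mean scaling into
#'   sub-batches (e.g. study phase); default: one batch.
#' @return numeric score per subject.
#' @examples
#' m <- data.frame(maob_sa = 1.4, tm1_sa = 1.3, apoe_e4_count = 1)
#' compute_score(m, 3)  # 1.4 + 1.3 + 1
#' @export
compute_score <- function(markers, model, norm_group = NULL) {
  if (!inherits(model, "score_model")) model <- score_model(model)
  missing_cols <- setdiff(model$components, names(markers))
  if (length(missing_cols))
    stop("marker table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  e4 <- markers$apoe_e4_count
  id <- model$model_id
  if (id == 0) return(as.numeric(e4))
  if (id == 1) return(as.numeric(markers$maob_sa))
  if (id == 2) return(markers$maob_sa + e4)
  if (id == 3) return(markers$maob_sa + markers$tm1_sa + e4)
  if (id == 4) return(markers$maob_sa + markers$tm1_sa + e4 +
                        markers$gsto1_a140_sa)
  if (id == 5) {
    branch <- ifelse(e4 == 0, markers$gsto1_a140_sa, markers$gsto1_d140_sa)
    return(markers$maob_sa + markers$tm1_sa + e4 + branch)
  }
  # model 6: mean-scaled normalized concentrations + weighted allele counts
  scale_by_mean <- function(v) {
    if (is.null(norm_group)) v / mean(v, na.rm = TRUE)
    else stats::ave(v, norm_group, FUN = function(z) z / mean(z, na.rm = TRUE))
  }
  maob_rel <- scale_by_mean(markers$maob_norm)
  tm1_rel <- scale_by_mean(markers$tm1_norm)
  w <- model$weights
  branch <- ifelse(e4 == 0,
                   w[["a140"]] * markers$gsto1_a140_count,
                   w[["d140"]] * markers$gsto1_d140_count)
  maob_rel + tm1_rel + e4 + branch
}

#' Evaluate a score model on a cohort
#'
#' Computes the composite scores, the full ROC evaluation ([roc_eval()]:
#' AUC, Hanley-McNeil CI, least-squares cut-off), and the Cohen's d of the
#' score distributions of the two groups.
#'
#' @inheritParams compute_score
#' @param labels group labels (positive class `"AD"` by default).
#' @param positive positive-class value, see [as_binary_labels()].
#' @return list of class `"model_eval"`: `model_id`, `roc` (a
#'   `"roc_result"`), `effect_size`, `scores`.
#' @export
evaluate_model <- function(markers, labels, model, norm_group = NULL,
                           positive = NULL) {
  if (!inherits(model, "score_model")) model <- score_model(model)
  y <- as_binary_labels(labels, positive)
  s <- compute_score(markers, model, norm_group = norm_group)
  if (sum(y == 1L, na.rm = TRUE) < 2L || sum(y == 0L, na.rm = TRUE) < 2L)
    stop("need at least 2 subjects per class")
  # constant (uninformative) scores have no defined effect size
  es <- tryCatch(cohens_d(s[y == 1L], s[y == 0L]),
                 error = function(e) structure(
                   list(d = NA_real_, mean1 = mean(s[y == 1L]),
                        mean2 = mean(s[y == 0L]), sd1 = 0, sd2 = 0),
                   class = "effect_size"))
  structure(list(model_id = model$model_id,
                 roc = roc_eval(s, y, positive = 1L),
                 effect_size = es, scores = s),
            class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("Score model %d\n", x$model_id))
  print(x$roc)
  cat(sprintf("effect size (Cohen's d) of scores: %.2f\n", x$effect_size$d))
  invisible(x)
}
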