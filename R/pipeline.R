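#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis on a cohort (simulated from a
#' [cohort_config()] or previously written tables): the two-stage spot
#' screen, score models with ROC evaluation per phase and pooled, a
#' Firth-penalized logistic regression over the model-5 components, biochip
#' normalization/genotyping with concordance against the subject genotypes,
#' and a 2D-DIGE-vs-biochip score scatter table. All outputs are plain
#' delimited text; a fixed seed yields an identical bundle.
#'
#' @param cohort an `"ad_cohort"`, a [cohort_config()] (simulated on the
#'   fly), or a directory path of written tables ([read_cohort()]).
#' @param outdir output directory, or `NULL` to skip writing.
#' @param models score models to evaluate (default 0:6).
#' @param alpha,ratio_hi,ratio_lo,matched_min,method screen thresholds, see
#'   [run_screen()].
#' @param verbose log per-stage progress and filter counts.
#' @return list (invisibly when writing): `screen`, `model_table`
#'   (per-model AUC/CI/ES per sample set), `firth`, `genotype_concordance`,
#'   `score_scatter`, `outdir`.
#' @export
run_pipeline <- function(cohort, outdir = NULL, models = 0:6, alpha = 0.05,
                         ratio_hi = 1.20, ratio_lo = 0.80,
                         matched_min = 0.80, method = "holm",
                         verbose = FALSE) {
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  subjects <- cohort$subjects
  say <- function(...) if (verbose) message(sprintf(...))

  say("[screen] two-stage spot screen on %d spots", nrow(cohort$spots$abundances))
  screen <- tryCatch(
    run_screen(cohort$spots, subjects, alpha = alpha, ratio_hi = ratio_hi,
               ratio_lo = ratio_lo, matched_min = matched_min,
               method = method, verbose = verbose),
    error = function(e) stop("stage 'screen': ", conditionMessage(e), call. = FALSE))
  say("[screen] %d candidates, %d confirmed",
      nrow(screen$candidates), nrow(screen$final))

  markers <- dige_markers(cohort$spots, subjects)
  panel_norm <- tryCatch(erk2_normalize(cohort$panel, apoe_norm = "pan_apoe"),
                         error = function(e) stop("stage 'biochip': ",
                                                  conditionMessage(e), call. = FALSE))
  geno <- call_genotypes(panel_norm)
  bmark <- biochip_markers(panel_norm, subjects)

  eval_rows <- list()
  for (m in models) {
    mt <- if (m == 6) bmark else markers
    if (m == 6 && is.null(cohort$panel)) stop("stage 'score': model 6 needs a biochip panel")
    for (set in c("discovery", "verification", "pooled")) {
      keep <- if (set == "pooled") rep(TRUE, nrow(subjects))
      else subjects$phase == set
      ev <- tryCatch(
        evaluate_model(mt[keep, , drop = FALSE], subjects$group[keep], m),
        error = function(e) stop(sprintf("stage 'score' (model %d, %s): %s",
                                         m, set, conditionMessage(e)), call. = FALSE))
      eval_rows[[length(eval_rows) + 1L]] <- data.frame(
        model = m, sample_set = set, n = sum(keep), auc = ev$roc$auc,
        se = ev$roc$se, ci_low = ev$roc$ci_low, ci_high = ev$roc$ci_high,
        cutoff = ev$roc$cutoff, sensitivity = ev$roc$sensitivity,
        specificity = ev$roc$specificity, effect_size = ev$effect_size$d)
    }
  }
  model_table <- do.call(rbind, eval_rows)
  say("[score] evaluated %d models on 3 sample sets", length(models))

  # Firth logistic regression over the model-5 component markers
  design <- data.frame(maob_sa = markers$maob_sa, tm1_sa = markers$tm1_sa,
                       apoe_e4_count = markers$apoe_e4_count,
                       gsto1_branch = ifelse(markers$apoe_e4_count == 0,
                                             markers$gsto1_a140_sa,
                                             markers$gsto1_d140_sa))
  cc <- stats::complete.cases(design)
  firth <- tryCatch(
    firth_fit(as.matrix(design[cc, ]), subjects$group[cc]),
    error = function(e) stop("stage 'firth': ", conditionMessage(e), call. = FALSE))
  firth_roc <- roc_eval(firth$probabilities, subjects$group[cc])
  say("[firth] AUC %.3f at cut-off %.3f", firth_roc$auc, firth_roc$cutoff)

  conc_e4 <- concordance(geno$apoe_e4_count, subjects$apoe_e4_count,
                         subjects$subject_id)
  conc_g <- concordance(geno$gsto1_a140_count, subjects$gsto1_a140_count,
                        subjects$subject_id)
  geno_table <- data.frame(
    locus = c("APOE_e4", "GSTO1_A140"),
    concordance = c(conc_e4$concordance, conc_g$concordance),
    n_called = c(conc_e4$n_called, conc_g$n_called),
    n_nocall = c(conc_e4$n_nocall, conc_g$n_nocall),
    discordant = c(paste(conc_e4$discordant, collapse = ";"),
                   paste(conc_g$discordant, collapse = ";")))
  say("[biochip] genotype concordance: APOE %.3f, GSTO1 %.3f",
      conc_e4$concordance, conc_g$concordance)

  scatter <- data.frame(
    subject_id = subjects$subject_id, group = subjects$group,
    score_dige = compute_score(markers, 5),
    score_biochip = compute_score(bmark, 6))

  out <- list(screen = screen, model_table = model_table, firth = firth,
              firth_roc = firth_roc, genotype_concordance = geno_table,
              score_scatter = scatter, outdir = outdir)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) utils::write.table(
      df, file.path(outdir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    wt(screen$pooled_stats, "spot_stats_pooled.tsv")
    wt(screen$candidates, "candidates.tsv")
    wt(screen$confirmed, "confirmed.tsv")
    wt(model_table, "model_roc.tsv")
    wt(geno_table, "genotype_concordance.tsv")
    wt(scatter, "score_scatter.tsv")
    wt(data.frame(term = names(firth$coefficients),
                  coefficient = firth$coefficients,
                  se = firth$standard_errors), "firth_coefficients.tsv")
    say("[report] bundle written to %s", outdir)
    return(invisible(out))
  }
  out
}
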