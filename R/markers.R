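#' Build a 2D-DIGE marker table for the score models
#'
#' Extracts the marker spots (by their `spot_info` names `MaoB`, `Tm1`,
#' `GSTO1_A140`, `GSTO1_D140`) from a spot matrix and joins the subjects'
#' allele counts, yielding the per-subject marker table consumed by
#' [compute_score()] for models 0--5.
#'
#' @param spots a `"spot_matrix"`.
#' @param subjects subject table (`subject_id`, `group`, `phase`,
#'   `apoe_e4_count`, `gsto1_a140_count`, `gsto1_d140_count`).
#' @return data.frame with one row per subject: SA columns `maob_sa`,
#'   `tm1_sa`, `gsto1_a140_sa`, `gsto1_d140_sa`, the allele counts, plus
#'   `subject_id`, `group`, `phase`.
#' @export
dige_markers <- function(spots, subjects) {
  stopifnot(inherits(spots, "spot_matrix"))
  row_of <- function(nm) {
    i <- match(nm, spots$spot_info$name)
    if (is.na(i)) rep(NA_real_, nrow(subjects))
    else spots$abundances[i, subjects$subject_id]
  }
  data.frame(subject_id = subjects$subject_id, group = subjects$group,
             phase = subjects$phase,
             maob_sa = row_of("MaoB"), tm1_sa = row_of("Tm1"),
             gsto1_a140_sa = row_of("GSTO1_A140"),
             gsto1_d140_sa = row_of("GSTO1_D140"),
             apoe_e4_count = subjects$apoe_e4_count,
             gsto1_a140_count = subjects$gsto1_a140_count,
             gsto1_d140_count = subjects$gsto1_d140_count,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build a biochip marker table for score model 6
#'
#' Combines ERK2-normalized MaoB and Tm1 concentrations with allele counts
#' (either biochip genotype calls or reference genotypes) into the marker
#' table consumed by [compute_score()] for model 6.
#'
#' @param panel normalized biochip panel ([erk2_normalize()] output, columns
#'   `maob_norm`, `tm1_norm`).
#' @param genotypes data.frame with `sample_id`, `apoe_e4_count`,
#'   `gsto1_a140_count`, `gsto1_d140_count` (e.g. [call_genotypes()] output
#'   or the subject table with `subject_id`).
#' @return data.frame with `maob_norm`, `tm1_norm` and the allele counts,
#'   aligned on sample id.
#' @export
biochip_markers <- function(panel, genotypes) {
  need <- c("maob_norm", "tm1_norm")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel lacks normalized column(s): ",
                         paste(miss, collapse = ", "))
  gid <- if ("sample_id" %in% names(genotypes)) genotypes$sample_id
  else genotypes$subject_id
  i <- match(panel$sample_id, gid)
  if (anyNA(i)) stop("genotypes missing for sample(s): ",
                     paste(panel$sample_id[is.na(i)], collapse = ", "))
  data.frame(sample_id = panel$sample_id,
             maob_norm = panel$maob_norm, tm1_norm = panel$tm1_norm,
             apoe_e4_count = genotypes$apoe_e4_count[i],
             gsto1_a140_count = genotypes$gsto1_a140_count[i],
             gsto1_d140_count = genotypes$gsto1_d140_count[i],
             stringsAsFactors = FALSE, row.names = NULL)
}
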