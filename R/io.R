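#' Write a cohort to delimited text files
#'
#' Writes `subjects.csv`, `panel.csv` (CSV) and `spots.tsv` (TSV; spots in
#' rows with `spot_id` and `name` columns, samples in columns, empty fields
#' for unmatched spots) into `dir`.
#'
#' @param cohort an `"ad_cohort"` (or a list with `subjects`, `spots`,
#'   `panel`).
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$panel, file.path(dir, "panel.csv"),
                   row.names = FALSE)
  sp <- cohort$spots
  tab <- data.frame(spot_id = sp$spot_info$spot_id, name = sp$spot_info$name,
                    sp$abundances, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, file.path(dir, "spots.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

.require_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(miss, collapse = ", ")))
}

#' Read a subject table
#'
#' @param path CSV with columns `subject_id`, `group` (`AD`/`control`),
#'   `phase` (`discovery`/`verification`), `apoe_e4_count`,
#'   `gsto1_a140_count` (further columns are kept).
#' @return validated data.frame (with `gsto1_d140_count` derived if absent).
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("subject_id", "group", "phase", "apoe_e4_count",
                      "gsto1_a140_count"), path)
  bad <- which(!df$group %in% c("AD", "control"))
  if (length(bad)) stop(sprintf("%s: column 'group', row %d: invalid value '%s'",
                                path, bad[1L], df$group[bad[1L]]))
  bad <- which(!df$phase %in% c("discovery", "verification"))
  if (length(bad)) stop(sprintf("%s: column 'phase', row %d: invalid value '%s'",
                                path, bad[1L], df$phase[bad[1L]]))
  for (cc in c("apoe_e4_count", "gsto1_a140_count")) {
    bad <- which(!df[[cc]] %in% 0:2)
    if (length(bad)) stop(sprintf("%s: column '%s', row %d: allele count must be 0/1/2",
                                  path, cc, bad[1L]))
  }
  if (!"gsto1_d140_count" %in% names(df))
    df$gsto1_d140_count <- 2L - df$gsto1_a140_count
  df
}

#' Read a spot-abundance matrix
#'
#' @param path TSV as written by [write_cohort()]: `spot_id`, `name`, then
#'   one column per sample; empty cells mark unmatched spots.
#' @return a `"spot_matrix"`.
#' @export
read_spot_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .require_cols(df, c("spot_id", "name"), path)
  m <- as.matrix(df[, setdiff(names(df), c("spot_id", "name")), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$name
  neg <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("%s: spot '%s', sample '%s': standardized abundances must be positive",
                 path, rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]))
  structure(list(abundances = m,
                 spot_info = data.frame(spot_id = df$spot_id, name = df$name,
                                        planted = NA, genotype_linked = NA_character_,
                                        stringsAsFactors = FALSE),
                 matched_fraction = rowMeans(!is.na(m))),
            class = "spot_matrix")
}

#' Read a biochip panel table
#'
#' @param path CSV with columns `sample_id`, `maob`, `tm1`, `gsto1_a140`,
#'   `erk2`, `apoe4`, `pan_apoe`, `ppp_dilution_factor`.
#' @return validated data.frame.
#' @export
read_biochip_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_cols(df, c("sample_id", "maob", "tm1", "gsto1_a140", "erk2",
                      "apoe4", "pan_apoe", "ppp_dilution_factor"), path)
  for (cc in c("maob", "tm1", "gsto1_a140", "erk2", "apoe4", "pan_apoe")) {
    bad <- which(!is.na(df[[cc]]) & df[[cc]] < 0)
    if (length(bad)) stop(sprintf("%s: column '%s', row %d: concentrations must be >= 0",
                                  path, cc, bad[1L]))
  }
  if (any(df$ppp_dilution_factor < 1))
    stop(path, ": ppp_dilution_factor must be >= 1")
  df
}

#' Read cohort tables from a directory
#'
#' Counterpart of [write_cohort()].
#'
#' @param dir directory holding `subjects.csv`, `spots.tsv`, `panel.csv`.
#' @return list with `subjects`, `spots`, `panel`.
#' @export
read_cohort <- function(dir) {
  list(subjects = read_subjects(file.path(dir, "subjects.csv")),
       spots = read_spot_matrix(file.path(dir, "spots.tsv")),
       panel = read_biochip_panel(file.path(dir, "panel.csv")))
}

#' Read a pipeline run configuration
#'
#' YAML file with any of the [cohort_config()] fields (under `cohort:`),
#' the models to evaluate (`models:`), screen thresholds (`alpha`,
#' `ratio_hi`, `ratio_lo`, `matched_min`), the p-adjustment `method`, and
#' `seed`.
#'
#' @param path YAML file.
#' @return list of class `"run_config"` with `cohort` (a
#'   [cohort_config()]), `models`, `alpha`, `ratio_hi`, `ratio_lo`,
#'   `matched_min`, `method`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- c(as.list(y$cohort), if (!is.null(y$seed)) list(seed = y$seed))
  cc <- do.call(cohort_config, args)
  cfg <- list(cohort = cc,
              models = if (is.null(y$models)) 0:6 else as.integer(y$models),
              alpha = y$alpha %||% 0.05, ratio_hi = y$ratio_hi %||% 1.20,
              ratio_lo = y$ratio_lo %||% 0.80,
              matched_min = y$matched_min %||% 0.80,
              method = y$method %||% "holm", seed = cc$seed)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
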