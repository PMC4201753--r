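#' Moment-matched positive abundance draws
#'
#' Samples positive values whose population mean and SD equal the requested
#' `mean` and `sd`. Spot standardized abundances (SA) are ratios to an
#' internal standard and therefore positive; a plain normal truncated at 0
#' would bias the realized moments whenever `sd` is large relative to `mean`,
#' so the latent normal parameters are solved so that the truncated
#' distribution has exactly the target moments. A zero-truncated normal
#' cannot have SD exceeding its mean; for such strongly dispersed targets
#' (cv close to or above 1, e.g. a spot down-regulated to ratio 0.55 with
#' d 0.73), and with `model = "lognormal"`, a moment-matched lognormal is
#' used instead.
#'
#' @param n number of draws.
#' @param mean,sd target mean (> 0) and SD (>= 0).
#' @param model `"truncnorm"` (lognormal only where the truncated normal is
#'   infeasible) or `"lognormal"` throughout.
#' @return numeric vector of `n` positive draws.
#' @export
rtnorm_moments <- function(n, mean, sd, model = c("truncnorm", "lognormal")) {
  model <- match.arg(model)
  if (mean <= 0) stop("mean must be positive")
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) return(rep(mean, n))
  if (model == "lognormal" || mean / sd <= 1.05) {
    s2 <- log(1 + (sd / mean)^2)
    return(stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2)))
  }
  par <- if (mean / sd > 6) list(mu = mean, sigma = sd)  # truncation mass < 1e-9
  else .tnorm_params(mean, sd)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(max(n, 16L), par$mu, par$sigma)
    out <- c(out, draw[draw > 0])
  }
  out[seq_len(n)]
}

# latent (mu, sigma) such that N(mu, sigma) truncated at 0 has given mean/sd
.tnorm_params <- function(m, s) {
  ratio_fun <- function(a) {
    h <- exp(stats::dnorm(a, log = TRUE) -
               stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
    (h - a) / sqrt(1 + a * h - h^2)
  }
  a <- stats::uniroot(function(a) ratio_fun(a) - m / s,
                      lower = -30, upper = 30, tol = 1e-12)$root
  h <- exp(stats::dnorm(a, log = TRUE) -
             stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  sigma <- s / sqrt(1 + a * h - h^2)
  list(mu = -a * sigma, sigma = sigma)
}

#' Specify a planted differential spot
#'
#' Describes one spot of the synthetic 2D-DIGE matrix. Quantitative planted
#' spots are parameterized by their AD/control abundance ratio and Cohen's d;
#' both groups share the SD `control_mean * |ratio - 1| / d`, which makes the
#' generated data reproduce the (ratio, d) pair simultaneously.
#' Genotype-linked spots instead scale with the subject's allele count:
#' `mean = base * max(count / 2, background)` with proportional noise
#' (`sd = noise_cv * mean`), emulating proteomic-genotyping isoform spots.
#'
#' @param spot_id integer spot index (1-based, `<= n_spots`).
#' @param name marker label (e.g. `"MaoB"`).
#' @param control_mean control-group mean SA (genotype-linked spots: the
#'   two-allele "base" level).
#' @param ad_control_ratio pooled AD/control ratio of mean SAs (> 0);
#'   ignored for genotype-linked spots.
#' @param effect_size_d Cohen's d of the pooled comparison (> 0 whenever
#'   `ad_control_ratio != 1`); fixes the common within-group SD
#'   `control_mean * |ad_control_ratio - 1| / effect_size_d`.
#' @param ratio_discovery,ratio_verification optional phase-specific AD
#'   ratios (screen hits typically differ between phases); default: the
#'   pooled ratio in both phases. The sample-size-weighted mixture of the
#'   phase ratios should equal the pooled ratio.
#' @param genotype_linked `NULL`, or one of `"APOE_e4"`, `"GSTO1_A140"`,
#'   `"GSTO1_D140"` naming the allele whose count drives the spot.
#' @param background relative background level for zero-allele-count
#'   subjects of a genotype-linked spot.
#' @param noise_cv proportional noise of a genotype-linked spot.
#' @return list of class `"planted_spot"`.
#' @export
planted_spot <- function(spot_id, name, control_mean = 1,
                         ad_control_ratio = 1, effect_size_d = 0,
                         ratio_discovery = NULL, ratio_verification = NULL,
                         genotype_linked = NULL, background = 0.05,
                         noise_cv = 0.15) {
  if (control_mean <= 0) stop("control_mean must be positive")
  if (ad_control_ratio <= 0) stop("ad_control_ratio must be positive")
  if (is.null(genotype_linked) && ad_control_ratio != 1 && effect_size_d <= 0)
    stop("effect_size_d must be positive when ad_control_ratio != 1 ",
         "(spot ", name, ")")
  if (!is.null(genotype_linked) &&
      !genotype_linked %in% c("APOE_e4", "GSTO1_A140", "GSTO1_D140"))
    stop("unknown genotype link: ", genotype_linked)
  if (xor(is.null(ratio_discovery), is.null(ratio_verification)))
    stop("supply both phase ratios or neither")
  structure(list(spot_id = as.integer(spot_id), name = name,
                 control_mean = control_mean,
                 ad_control_ratio = ad_control_ratio,
                 effect_size_d = effect_size_d,
                 ratio_discovery = ratio_discovery %||% ad_control_ratio,
                 ratio_verification = ratio_verification %||% ad_control_ratio,
                 genotype_linked = genotype_linked,
                 background = background, noise_cv = noise_cv),
            class = "planted_spot")
}

#' Default planted-spot panel
#'
#' The six-marker panel mirroring the verified screen hits and the two
#' GSTO1 isoform spots: MaoB (pooled ratio 1.38, d 1.27), ApoE3 (0.55,
#' 0.73), Tm1 (1.29, 0.76), plus genotype-linked ApoE4 (APOE e4 count;
#' background 0.2 of the homozygote level), GSTO1*A140 and GSTO1*D140
#' (rs4925 isoform spots). The within-group SD of each quantitative spot is
#' fixed by the pooled (ratio, d) pair so the generated data reproduce both
#' columns; phase-specific ratios can be planted via [planted_spot()].
#'
#' @return list of [planted_spot()] objects.
#' @export
default_planted_spots <- function() {
  list(
    planted_spot(645L, "MaoB", 1, 1.38, 1.27),
    planted_spot(642L, "ApoE3", 1, 0.55, 0.73),
    planted_spot(655L, "Tm1", 1, 1.29, 0.76),
    planted_spot(629L, "ApoE4", 1, genotype_linked = "APOE_e4",
                 background = 0.2),
    planted_spot(698L, "GSTO1_A140", 1, genotype_linked = "GSTO1_A140"),
    planted_spot(700L, "GSTO1_D140", 1, genotype_linked = "GSTO1_D140"))
}

#' Cohort generator configuration
#'
#' Bundles every parameter of the synthetic cohort: group sizes of the
#' two study phases, APOE e4 allele-count distributions, GSTO1 rs4925 A140
#' allele frequencies per disease-by-carrier stratum (the e4-negative AD
#' stratum is forced to frequency 1), the planted-spot panel, spot noise and
#' missingness, platelet-count distribution, and biochip assay noise.
#'
#' @param n_ad_discovery,n_co_discovery,n_ad_verification,n_co_verification
#'   group sizes (defaults 22/25 and 40/38).
#' @param n_spots number of 2D-DIGE spots (default 890).
#' @param apoe_freqs list with elements `AD` and `control`, each a
#'   probability vector over allele counts 0/1/2. Defaults: AD
#'   `c(20, 30, 12)/62`, controls `c(56, 7, 0)/63`.
#' @param gsto1_a140_allele_freq named vector of A140 allele frequencies for
#'   strata `ad_e4neg` (forced to 1), `ad_e4pos`, `co_e4neg`, `co_e4pos`.
#' @param planted_effects list of [planted_spot()]; default
#'   [default_planted_spots()].
#' @param spot_noise_sd SD of null-spot abundances (SA units).
#' @param missing_rate probability a spot is unmatched in a sample.
#' @param platelet_mean,platelet_sd platelet count distribution
#'   (platelets/ul; defaults 363e3 and 131e3).
#' @param biochip_cv multiplicative assay CV of the biochip (default 0.10).
#' @param ppp_dilution_factor dilution factor of the plasmatic fraction.
#' @param noise_model abundance noise model: `"truncnorm"` (moment-matched
#'   zero-truncated normal, lognormal where infeasible) or `"lognormal"`.
#' @param seed integer RNG seed used by [generate_cohort()].
#' @return validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_ad_discovery = 22L, n_co_discovery = 25L,
                          n_ad_verification = 40L, n_co_verification = 38L,
                          n_spots = 890L,
                          apoe_freqs = list(AD = c(20, 30, 12) / 62,
                                            control = c(56, 7, 0) / 63),
                          gsto1_a140_allele_freq = c(ad_e4neg = 1.0,
                                                     ad_e4pos = 0.32,
                                                     co_e4neg = 0.38,
                                                     co_e4pos = 0.38),
                          planted_effects = default_planted_spots(),
                          spot_noise_sd = 0.25, missing_rate = 0.05,
                          platelet_mean = 363e3, platelet_sd = 131e3,
                          biochip_cv = 0.10, ppp_dilution_factor = 10,
                          noise_model = c("truncnorm", "lognormal"),
                          seed = 1L) {
  noise_model <- match.arg(noise_model)
  ns <- c(n_ad_discovery, n_co_discovery, n_ad_verification, n_co_verification)
  if (any(ns < 1)) stop("all group sizes must be positive")
  if (!all(c("AD", "control") %in% names(apoe_freqs)))
    stop("apoe_freqs needs elements 'AD' and 'control'")
  for (g in c("AD", "control")) {
    f <- apoe_freqs[[g]]
    if (length(f) != 3L || any(f < 0) || abs(sum(f) - 1) > 1e-8)
      stop("apoe_freqs$", g, " must be 3 probabilities over counts 0/1/2 summing to 1")
  }
  gf <- gsto1_a140_allele_freq
  req <- c("ad_e4neg", "ad_e4pos", "co_e4neg", "co_e4pos")
  if (!all(req %in% names(gf))) stop("gsto1_a140_allele_freq needs strata: ",
                                     paste(req, collapse = ", "))
  if (any(gf < 0 | gf > 1)) stop("allele frequencies must lie in [0, 1]")
  gf["ad_e4neg"] <- 1.0  # e4-negative AD stratum is homozygous A140 by design
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (spot_noise_sd <= 0) stop("spot_noise_sd must be positive")
  if (biochip_cv < 0) stop("biochip_cv must be non-negative")
  if (ppp_dilution_factor < 1) stop("ppp_dilution_factor must be >= 1")
  defaulted_spots <- missing(planted_effects)
  ids <- vapply(planted_effects, `[[`, 1L, "spot_id")
  if (anyDuplicated(ids)) stop("planted spot ids must be unique")
  if (length(ids) && any(ids < 1L | ids > n_spots)) {
    if (defaulted_spots && length(ids) <= n_spots) {
      # default panel on a reduced matrix: renumber the marker spots
      for (i in seq_along(planted_effects))
        planted_effects[[i]]$spot_id <- i
    } else {
      stop("planted spot ids must lie in 1..n_spots")
    }
  }
  structure(list(n_ad_discovery = n_ad_discovery,
                 n_co_discovery = n_co_discovery,
                 n_ad_verification = n_ad_verification,
                 n_co_verification = n_co_verification,
                 n_spots = as.integer(n_spots), apoe_freqs = apoe_freqs,
                 gsto1_a140_allele_freq = gf,
                 planted_effects = planted_effects,
                 spot_noise_sd = spot_noise_sd, missing_rate = missing_rate,
                 platelet_mean = platelet_mean, platelet_sd = platelet_sd,
                 biochip_cv = biochip_cv,
                 ppp_dilution_factor = ppp_dilution_factor,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "cohort_config")
}

# demographics of the two phases (reporting only; never used by any score)
.demographics <- list(
  AD = list(discovery = list(mmse = c(5.5, 4.2), age = c(81, 8.2), female = 0.82),
            verification = list(mmse = c(14, 7.1), age = c(82, 6.2), female = 0.81)),
  control = list(discovery = list(mmse = c(29, 0.8), age = c(80, 8.5), female = 0.86),
                 verification = list(mmse = c(29, 0.9), age = c(81, 6.3), female = 0.81)))

.rtrunc_range <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(max(n, 16L), mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

# unit-mean multiplicative lognormal noise
.lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

#' Generate a synthetic cohort
#'
#' Draws subjects (diagnosis, phase, genotypes, demographics, platelet
#' counts), a spots-by-samples 2D-DIGE SA matrix with planted differential
#' and genotype-linked spots among null spots, and a multiplex biochip panel
#' that re-measures the same latent marker levels with assay noise
#' (`biochip_cv`) after scaling cellular analytes by each sample's platelet
#' count (the variation the ERK2 loading control later removes).
#'
#' @param config a [cohort_config()].
#' @return list of class `"ad_cohort"`: `subjects` (data.frame), `spots`
#'   (a `"spot_matrix"`: `abundances` matrix with NAs for unmatched spots,
#'   `spot_info`, `matched_fraction`), `panel` (biochip data.frame), and the
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  grp <- c(rep("AD", config$n_ad_discovery), rep("control", config$n_co_discovery),
           rep("AD", config$n_ad_verification), rep("control", config$n_co_verification))
  phs <- rep(c("discovery", "discovery", "verification", "verification"),
             c(config$n_ad_discovery, config$n_co_discovery,
               config$n_ad_verification, config$n_co_verification))
  n <- length(grp)
  sid <- sprintf("S%03d", seq_len(n))

  e4 <- integer(n)
  for (g in c("AD", "control")) {
    idx <- grp == g
    e4[idx] <- sample(0:2, sum(idx), replace = TRUE, prob = config$apoe_freqs[[g]])
  }
  stratum <- paste0(ifelse(grp == "AD", "ad_", "co_"),
                    ifelse(e4 == 0, "e4neg", "e4pos"))
  a140 <- stats::rbinom(n, 2L, config$gsto1_a140_allele_freq[stratum])

  mmse <- age <- numeric(n); sex <- character(n)
  for (g in c("AD", "control")) for (p in c("discovery", "verification")) {
    idx <- grp == g & phs == p
    d <- .demographics[[g]][[p]]
    mmse[idx] <- round(.rtrunc_range(sum(idx), d$mmse[1], d$mmse[2], 0, 30))
    age[idx] <- round(.rtrunc_range(sum(idx), d$age[1], d$age[2], 40, 105))
    sex[idx] <- ifelse(stats::runif(sum(idx)) < d$female, "F", "M")
  }
  platelets <- .rtrunc_range(n, config$platelet_mean, config$platelet_sd,
                             1, Inf)

  subjects <- data.frame(subject_id = sid, group = grp, phase = phs,
                         apoe_e4_count = e4, gsto1_a140_count = a140,
                         gsto1_d140_count = 2L - a140, mmse = mmse,
                         age = age, sex = sex, platelet_count = platelets,
                         stringsAsFactors = FALSE)

  abund <- matrix(NA_real_, nrow = config$n_spots, ncol = n,
                  dimnames = list(sprintf("spot_%04d", seq_len(config$n_spots)), sid))
  spot_info <- data.frame(spot_id = seq_len(config$n_spots),
                          name = rownames(abund), planted = FALSE,
                          genotype_linked = NA_character_,
                          stringsAsFactors = FALSE)
  allele_count <- function(link) switch(link,
    APOE_e4 = e4, GSTO1_A140 = a140, GSTO1_D140 = 2L - a140)
  planted_ids <- integer(0)
  for (ps in config$planted_effects) {
    i <- ps$spot_id
    planted_ids <- c(planted_ids, i)
    spot_info$name[i] <- ps$name
    spot_info$planted[i] <- TRUE
    rownames(abund)[i] <- ps$name
    if (!is.null(ps$genotype_linked)) {
      spot_info$genotype_linked[i] <- ps$genotype_linked
      cnt <- allele_count(ps$genotype_linked)
      m <- ps$control_mean * pmax(cnt / 2, ps$background)
      abund[i, ] <- vapply(m, function(mi)
        rtnorm_moments(1L, mi, ps$noise_cv * mi), 1)
    } else {
      sd_sp <- if (ps$ad_control_ratio == 1) config$spot_noise_sd
      else ps$control_mean * abs(ps$ad_control_ratio - 1) / ps$effect_size_d
      ratio_phase <- ifelse(phs == "discovery", ps$ratio_discovery,
                            ps$ratio_verification)
      mu <- ifelse(grp == "AD", ps$control_mean * ratio_phase,
                   ps$control_mean)
      for (lev in unique(mu)) {
        idx <- mu == lev
        abund[i, idx] <- rtnorm_moments(sum(idx), lev, sd_sp, config$noise_model)
      }
    }
  }
  null_rows <- setdiff(seq_len(config$n_spots), planted_ids)
  if (length(null_rows)) {
    draws <- rtnorm_moments(length(null_rows) * n, 1, config$spot_noise_sd, config$noise_model)
    abund[null_rows, ] <- matrix(draws, nrow = length(null_rows))
  }

  latent <- abund  # biochip re-measures these latent marker levels
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(length(abund)) < config$missing_rate,
                   nrow = nrow(abund))
    abund[miss] <- NA_real_
  }
  spots <- structure(list(abundances = abund, spot_info = spot_info,
                          matched_fraction = rowMeans(!is.na(abund))),
                     class = "spot_matrix")

  marker_row <- function(nm) {
    i <- match(nm, spot_info$name)
    if (is.na(i)) rep(NA_real_, n) else latent[i, ]
  }
  pscale <- platelets / config$platelet_mean
  cv <- config$biochip_cv
  panel <- data.frame(
    sample_id = sid,
    maob = marker_row("MaoB") * pscale * .lnorm_noise(n, cv),
    tm1 = marker_row("Tm1") * pscale * .lnorm_noise(n, cv),
    gsto1_a140 = pmax(a140 / 2, 0.05) * pscale * .lnorm_noise(n, cv),
    erk2 = pscale * .lnorm_noise(n, cv),
    apoe4 = pmax(e4 / 2, 0.2) * .lnorm_noise(n, cv),
    pan_apoe = .lnorm_noise(n, cv),
    ppp_dilution_factor = config$ppp_dilution_factor,
    platelet_count = platelets,
    stringsAsFactors = FALSE)

  structure(list(subjects = subjects, spots = spots, panel = panel,
                 config = config),
            class = "ad_cohort")
}

#' @export
print.ad_cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("Synthetic platelet cohort: %d subjects (%d AD / %d controls), %d spots\n",
              nrow(s), sum(s$group == "AD"), sum(s$group == "control"),
              nrow(x$spots$abundances)))
  cat(sprintf("phases: discovery %d/%d, verification %d/%d; seed %d\n",
              sum(s$group == "AD" & s$phase == "discovery"),
              sum(s$group == "control" & s$phase == "discovery"),
              sum(s$group == "AD" & s$phase == "verification"),
              sum(s$group == "control" & s$phase == "verification"),
              x$config$seed))
  invisible(x)
}

#' Generate an ERK2 dilution series
#'
#' Emulates repeated biochip analysis of two-fold dilutions of a concentrated
#' platelet-rich-plasma sample: the ERK2 signal is proportional to the
#' platelet count with multiplicative noise of the given CV.
#'
#' @param n_steps number of dilution steps (>= 3).
#' @param cv multiplicative assay CV (>= 0).
#' @param seed RNG seed.
#' @param start_platelets platelet count of the undiluted sample
#'   (platelets/ul).
#' @param erk2_per_platelet proportionality constant.
#' @return data.frame with `platelet_count` and `erk2_signal`.
#' @export
generate_dilution_series <- function(n_steps, cv, seed = 1L,
                                     start_platelets = 8e5,
                                     erk2_per_platelet = 2e-6) {
  if (n_steps < 3L) stop("need at least 3 dilution steps")
  if (cv < 0) stop("cv must be non-negative")
  set.seed(seed)
  platelet_count <- start_platelets / 2^(seq_len(n_steps) - 1L)
  data.frame(platelet_count = platelet_count,
             erk2_signal = erk2_per_platelet * platelet_count *
               .lnorm_noise(n_steps, cv))
}
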