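---
title: "Methods: platelet proteome screening and composite AD scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: platelet proteome screening and composite AD scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateletAD)
```

## Scope and model

plateletAD implements a blood-based biomarker workflow for late-onset
Alzheimer's disease (LOAD) built on the platelet proteome. Its statistical
core is:

1. a **two-stage differential-abundance screen** over 2D-DIGE spot maps
   (discovery cohort, then an independent verification cohort, then the
   pooled collective),
2. **composite diagnostic sum scores** (models 0–6) combining spot
   standardized abundances (SA) with the *APOE* ε4 allele count, including a
   decision tree that branches on ε4 carrier status to pick a GSTO1 rs4925
   isoform term,
3. **Firth-penalized logistic regression** as the regression alternative to
   the plain sum score,
4. nonparametric **ROC evaluation** with least-squares cut-off selection,
   and
5. **multiplex biochip processing**: 4PL calibration, ERK2 loading-control
   normalization, and proteomic genotyping with concordance assessment.

Because no subject-level data are published for this design, the package
ships a synthetic cohort generator whose defaults encode the printed study
conditions (group sizes 22/25 and 40/38; AD ε4 allele-count distribution
20/30/12 of 62; control distribution 56/7/0 of 63; GSTO1*A140 allele
frequency 1.0 in ε4-negative AD, 0.32 in ε4-positive AD, 0.38 in controls;
890 spots with the four verified markers planted at their pooled
(ratio, Cohen's d) pairs; platelet counts 363 ± 131 × 10³/µl; 10 % biochip
assay CV). Everything downstream is exercised and tested against this
generator.

## Elementary statistics

All group comparisons are Mann–Whitney U tests (the abundance data are not
Gaussian; `ks_normality()` provides the pre-check, with the caveat that the
classical KS p-value with estimated parameters is conservative — a
Lilliefors variant is available). The U statistic counts pairs favouring the
first sample with ties as ½; for combined n ≤ 12 the two-sided p-value is
computed by exhaustive enumeration of group assignments, above that by the
tie-corrected normal approximation without continuity correction. Effect
sizes are Cohen's d in the average-SD form
`(mean1 − mean2) / ((SD1 + SD2) / 2)`. Multiplicity control uses Holm's
step-down by default (`adjust_pvalues()`, with Bonferroni/Hochberg/BH
selectable) and makes the family size `m` explicit, because the screen
adjusts small candidate sets against large universes. Genotype tables are
compared by Pearson chi-square after adding 0.5 to empty cells only (the
all-cell Haldane–Anscombe variant is a flag).

A note on invariants: step-down adjustments are order-preserving and
dominate the raw p-values, but they are *not* idempotent — re-adjusting an
already-adjusted vector inflates it again. The test-suite asserts order
preservation and dominance only.

## The two-stage screen

`spot_stats()` computes, per spot and per phase, the AD/control ratio of
group mean SAs (ratio of means, not mean of ratios — stable under
missingness), the Mann–Whitney p, the rank-based AUC and Cohen's d, on
complete cases per spot; 2D-DIGE missingness is spot-wise (unmatched spots),
so no imputation is attempted. Filter criteria:

* (a) spot matched in **more than 80 %** of all gels (flagged otherwise,
  never silently dropped),
* (b) SA ratio **> 1.20 or < 0.80** (strict),
* (c) unadjusted discovery **p < 0.05**,
* (d) verification p, Holm-adjusted over the number of discovery
  candidates, **< 0.05**,
* (e) pooled p, Holm-adjusted over the full matched-spot universe
  (890 by default), **< 0.05**.

A practical observation from the simulations: with the verified markers
planted at their pooled effect sizes, the two weaker ones (d ≈ 0.73–0.76)
have only ~50–60 % power against gate (e) at n = 62/63 — their printed
adjusted pooled p-values (0.001–0.010) are themselves close to the 0.05
line. Full-panel recovery of at least three of the four markers therefore
occurs in roughly two-thirds of simulated cohorts, not almost always; this
is an inherent property of two-stage designs run at the edge of their
power, not a defect of the filter chain.

## Score models

With `e4` the *APOE* ε4 allele count and SAs from the marker spots:

| model | score |
|---|---|
| 0 | `e4` |
| 1 | MaoB |
| 2 | MaoB + `e4` |
| 3 | MaoB + Tm1 + `e4` |
| 4 | model 3 + GSTO1*A140 SA |
| 5 | model 3 + (A140 SA if `e4 = 0`, else D140 SA) |
| 6 | MaoB* + Tm1* + `e4` + (0.6·A140 count if `e4 = 0`, else 0.9·D140 count) |

The ε4 allele count replaces the ApoE4 spot SA inside all sum scores
because the gel region of that spot carries considerable background signal
in ε4-negative subjects. Down-regulated markers enter sum scores with their
raw SAs (not negated); orientation handling applies only when a single
down-regulated marker is evaluated alone by ROC. In model 6, MaoB* and Tm1*
are ERK2-normalized biochip concentrations divided by their average over
the analyzed batch (all samples by default; a `norm_group` argument allows
phase-wise means — we default to the single batch because that is how one
biochip run is processed). The 0.6/0.9 weights translate the A140/D140
allele counts to the SA scale of the corresponding gel spots.

## Firth-penalized logistic regression

`firth_fit()` maximizes `l(β) + ½ log det I(β)` by Newton–Raphson on the
hat-adjusted score `X'(y − p + h(½ − p))`, with step-halving whenever a
step would decrease the penalized likelihood; convergence is declared when
the largest coefficient change falls below 1e-8 (50 iterations cap,
non-convergence flagged and the current iterate returned). Predictors are
standardized internally for conditioning and back-transformed, including
the covariance. The penalty makes estimates finite under the complete
separation that small, well-separated cohorts produce. The reported
penalized likelihood is corrected for the standardization Jacobian
(`log det I` shifts by a constant under linear reparameterization), so it
matches the value on the original scale.

## ROC machinery

AUC is the rank statistic `P(score_AD > score_Co) + ½ P(tie)`, identical to
the trapezoidal area under the empirical ROC curve. Standard errors are
Hanley–McNeil by default (DeLong's placement-value variance is an option),
with normal 95 % CIs clipped to [0, 1]. The "least-squares" cut-off
minimizes `(1 − sensitivity)² + (1 − specificity)²` — the squared Euclidean
distance to the ideal ROC corner (0, 1) — over midpoints between adjacent
distinct scores, ties broken toward higher sensitivity; subjects at or
above the cut-off are called positive. The cut-off search is pinned by an
exhaustive-search oracle in the tests, so this reading of "least squares"
is enforced rather than assumed.

## Biochip processing

Calibration curves are four-parameter logistics fitted by
Levenberg–Marquardt least squares; quantification inverts the curve inside
the calibrated range only (signals at or beyond the asymptotes are flagged
out-of-range, never extrapolated) and multiplies plasmatic analytes by the
PPP dilution factor. `erk2_normalize()` divides cellular analytes by the
sample's ERK2 concentration, cancelling per-sample platelet-load factors
exactly (an algebraic identity tested as such); the plasmatic ApoE4 analyte
can be normalized by panApoE instead — the pipeline default, since dividing
a plasma analyte by a platelet-proportional control re-introduces
platelet-count variation. Genotypes are called from normalized isoform
levels by a two-threshold rule; thresholds are learned by a 1-D 3-cluster
partition when not fixed, and values inside a guard band around a threshold
become no-calls excluded from concordance denominators.

## The synthetic generator: what it emulates, and what not

Spot abundances are positive SA-scale values. Null spots draw from a
distribution with mean 1 and SD 0.25 (chosen to match the scale of the
implied marker SDs, 0.30–0.62). Planted spots use the common within-group
SD `control_mean·|ratio − 1|/d`, which reproduces the printed ratio and
Cohen's d simultaneously. Sampling uses a **moment-matched zero-truncated
normal**: the latent normal parameters are solved so the realized mean/SD
equal the targets (naive truncation would bias strong down-regulated spots
badly). A zero-truncated normal cannot have SD ≥ mean, so for targets with
cv near or above 1 (the ApoE3 spot) the sampler switches to a
moment-matched lognormal; a full-lognormal mode is a config option.

Genotype-linked spots (ApoE4, the GSTO1 isoforms) scale with allele count:
`mean = base·max(count/2, background)` with *proportional* noise (cv 0.15)
— additive noise with a fixed SD cannot be represented at the near-zero
background level, and proportional scatter matches the clean per-genotype
clusters that make proteomic genotyping feasible. The ApoE4 spot's
background is 0.2 of the homozygote level (the gel region is noisy);
GSTO1 backgrounds are 0.05. GSTO1 genotypes are drawn per stratum under
Hardy–Weinberg at the stated allele frequencies, with the ε4-negative AD
stratum forced homozygous A140; both control strata use the overall control
frequency 0.38 (the printed 30 % for ε4-negative controls, combined with
38 % overall, would imply a near-1.0 frequency in the 7 ε4-positive
controls — a rounding artifact of tiny strata we do not reproduce).

The biochip panel re-measures the same subjects: quantitative analytes take
the gel-realized latent level (shared biological variation between the two
platforms, hence correlated gel and chip scores), genotype-linked analytes
the genotype-determined level, both scaled by the sample's platelet count
(cellular analytes only), multiplied by unit-mean lognormal assay noise of
the configured CV. MMSE, age and sex are simulated per phase from the
printed summaries for reporting only; no score uses them.

Passing tests on this generator demonstrate that the statistical pipeline
is correct under the stated distributional structure — independent markers,
exchangeable subjects, missingness independent of group. Real 2D-DIGE data
add gel batch effects, correlated spots, informative missingness and
covariate structure that the generator deliberately omits; results on it
say nothing about clinical validity.

## Numerical choices and problem sizes

Exact Mann–Whitney enumeration is limited to combined n ≤ 12 (924
assignments at worst, so the permutation oracle stays cheap). Newton
iterations use step-halving down to 1e-10 of the step. Cut-off ties are
broken toward sensitivity. The test-suite uses: 200 replicate cohorts for
the model-2 AUC, 100 each for models 5 and 6, 1e5 per group for the
binormal check, n = 1000–5000 per group for generator round-trips
(replicate-averaged where a single cohort's estimator noise is of the same
order as the recovery band), 30 seeds for screen recovery and 20 for null
screens — sizes at which Monte-Carlo error is comfortably below the asserted
tolerances.

## Known limitations

* The generator treats markers as conditionally independent given genotype;
  real MaoB/Tm1 abundances are likely correlated, which would lower
  combined-score AUCs somewhat.
* Calibration/quantification and the concentration-valued panel are linked
  only loosely: the generator emits concentrations directly, so 4PL fitting
  is exercised on synthetic calibrator series rather than end-to-end.
* Firth SEs come from the inverse Fisher information at the penalized
  optimum; profile-likelihood intervals (preferable near separation) are
  not implemented.
* The sample-size machinery of the original two-stage design is out of
  scope, as are gel image processing and MS identification.
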