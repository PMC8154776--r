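---
title: "Predicting microalbuminuria from proteinuria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microalbuminuria from proteinuria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microalb)
```

## The problem

Microalbuminuria — a urinary albumin-to-creatinine ratio (uACR) of 30–299
mg/gCr — marks the transition from normal to moderately increased
albuminuria in chronic kidney disease and is an independent risk factor for
kidney failure and cardiovascular disease. In several health systems,
however, the uACR is not routinely reimbursed for non-diabetic patients,
while the cheaper urinary protein-to-creatinine ratio (uPCR) is. The
conventional equivalence (uPCR 0.15 g/gCr for uACR 30 mg/gCr) has never
been well supported at low proteinuria levels, where protein assays lose
accuracy and the albumin fraction of urinary protein varies.

`microalb` implements the analysis chain needed to study this question on
repeated spot-urine measurements: unit-correct ratio derivation,
repeated-measurement albuminuria classification, a log-log piecewise
calibration of median uACR on uPCR, empirical ROC/Youden cutoff machinery
with DeLong comparisons, a same-sample stability substudy, and seeded
synthetic-data generators so the full pipeline is testable without patient
data.

## Data model and classification rules

A cohort is a per-visit table: each visit carries urinary protein (mg/dl),
urinary albumin (mg/l) and urinary creatinine (mg/dl), plus serum
creatinine, age, sex and a diabetes flag. Ratios are derived as
uPCR = uP/uCr (g/gCr) and uACR = uAlb × 100 / uCr (mg/gCr). Concentrations
below the assay detection limit are carried as numeric zero with a
censoring flag, and enter downstream analyses as zero; the single exception
is any ratio-of-ratios computation, which cannot use a zero denominator.
The detection limits themselves are configurable generator parameters
(defaults 1 mg/dl protein, 1 mg/l albumin), since assay sensitivities
differ between laboratories.

eGFR uses the Japanese Society of Nephrology equation
`194 · sCr^-1.094 · age^-0.287` (× 0.739 for women); the constants are
pluggable for other populations. The GFR category is taken from the mean of
all available eGFR values (the alternative — averaging only the three urine
visits — changes nothing material, and using every value is the less wasteful
convention), with standard half-open KDIGO bands (G2 = [60, 90) and so on).

Eligibility mirrors the target study population: first-visit uPCR below 0.5
g/gCr and first-visit eGFR of at least 15 ml/min/1.73 m²; patients whose
eGFR fell by 30% or more between measurements at most 92 days apart are
excluded (rapid progressors are a different clinical entity); a uPCR rising
past 0.5 g/gCr on a later visit does not exclude.

The patient-level albuminuria category uses the repeated-measurement rule:
whichever of normo (< 30), micro (30–299) or macro (≥ 300 mg/gCr) occurs on
at least two of the three visits; when the three visits produce one of
each, the patient is classified micro. The rule is permutation-invariant in
the three values.

## The calibration spline

The relationship between uPCR and the *median* uACR is summarised by
binning uPCR at 0.01 g/gCr resolution (a pair belongs to the bin whose
label is its uPCR rounded to the nearest 0.01 — labels are single values,
not ranges) and fitting, on the natural-log scale, a continuous piecewise
linear model of ln(median uACR) on ln(uPCR):

* the basis is the mkspline-style one, where each basis column has unit
  slope inside one segment, so each coefficient *is* a segment slope and
  continuity at the knots is structural, not a constraint to verify;
* knots sit at standard percentiles of the raw measurement distribution
  (5/35/65/95 for four knots, 10/50/90 for three, 5/27.5/50/72.5/95 for
  five), with type-7 (linearly interpolated) quantiles — the same
  interpolation rule used for all IQRs in the package;
* the knot count is chosen by Gaussian OLS AIC, `n·ln(RSS/n) + 2(p+1)`,
  computed identically for the linear and restricted-cubic kinds so the
  comparison is like for like; ties go to fewer knots;
* the restricted cubic alternative uses the truncated-power natural-spline
  basis (linear beyond the boundary knots), as a check that the piecewise
  linear summary is not an artefact of the basis;
* the fit is unweighted over occupied bins up to 0.50 g/gCr (weighting by
  bin size is available but off by default: the estimand is the median
  *curve*, and the sparse upper bins are exactly where a size-weighted fit
  would give up resolution). Bins with an undetected (zero) uPCR label are
  excluded — their logarithm is undefined.

Slope changes at the knots are tested with the contrast `c'β` on the basis
coefficients, `SE = sqrt(c'Vc)` from the OLS covariance, and a
t-distribution on the residual degrees of freedom.

Forward prediction evaluates `exp(intercept + slope·ln uPCR)` in the
segment covering the query; inversion solves the same equation segment-wise
in closed form and requires every slope to be positive. Neither
extrapolates beyond the stated domain (1–500 mg/gCr for the bundled
models); the synthetic generator, which needs a truth value everywhere,
extends the boundary segments linearly through an internal flag.

A JSON registry ships the published four-knot calibrations for the
combined, non-diabetic and diabetic populations. Under those coefficients a
median uACR of 30 mg/gCr corresponds to a uPCR of 0.077 g/gCr (combined) —
half the conventional 0.15 g/gCr equivalence — and uPCR 0.15 g/gCr already
corresponds to a median uACR of 78 mg/gCr. The acceptance script recomputes
these and the other worked values at run time.

## ROC machinery

The ROC module is deliberately self-contained. Thresholds are the unique
observed scores plus a sentinel above the maximum; a subject is called
positive when its score is at or above the threshold. This convention makes
the Youden tie-break ("among equal J, take the larger sensitivity")
equivalent to taking the lowest tying threshold. The AUC is the
Mann-Whitney statistic (ties count one half); its standard error and the
comparison of two correlated AUCs use the DeLong structural-components
estimator, with Hanley-McNeil available as an option. The p value against
AUC = 0.5, and the paired-test p value, use the normal approximation,
two-sided. Cutoffs are never rounded internally; assay-reporting precision
(two decimals for uPCR in g/gCr, integers for uACR) is applied only at
presentation.

The per-measurement threshold table pools every visit as an independent
record (matching the design it emulates, which reports n = patients ×
visits without clustering correction); the patient-level table evaluates
ten discriminators — the three single uPCRs, three pairwise sums, the
triple sum, and the three single uACRs — against the patient-level label,
with all pairwise DeLong comparisons. Subgroup tables repeat the parent
computation inside partitions by age band ([18, 65), [65, 80), ≥ 80), sex,
GFR stage (G1-3a vs G3b-4) or diabetes; single-class subgroups are flagged
rather than computed.

## Stability substudy

Each sample is assayed four times: fresh; after 3–4 h refrigerated; and
twice consecutively after freeze-thaw on day 3 or 4. Agreement between an
occasion pair is summarised per concentration stratum — protein bands at 3
and 8 mg/dl, albumin at 15 and 40 mg/l, creatinine at 50 and 90 mg/dl,
uPCR (and the uACR rows) split at mean uPCR 0.15 g/gCr — where the stratum
is assigned by the mean of the two compared measurements. Each summary is
the OLS line of the later on the earlier measurement, the Pearson r (the
natural scale matches the reported regression lines; rank correlation would
not), and the median/IQR of the bias, defined as later minus earlier. The
uCr/sCr urine-concentration index uses the single day-0 serum creatinine
(the substudy draws blood once; carrying one sCr keeps the index a property
of the urine sample).

## What the synthetic generators emulate — and what they do not

The cohort generator is the package's stand-in for the undeposited patient
data, and its defaults are the study conditions, fixed once:

* 197 non-diabetic and 106 diabetic patients, three visits at intervals of
  roughly 84 and 75 days (sd 35, floor 14);
* ln uPCR (mg/gCr) with population mean 4.44 and total sd 0.9, split 0.7
  between / 0.55 within patients — this reproduces percentiles 5/35/65/95
  at 20/60/120/350 mg/gCr, the documented knot locations;
* median uACR given uPCR follows the bundled piecewise log-linear
  calibration of the patient's stratum, with a ln-scale residual of sd 0.6
  split into a patient effect (0.45) and visit noise (0.40). The 0.6 was
  calibrated once so that synthetic bin IQR ratios resemble the reported
  bin IQRs (e.g. roughly 25–57 around a median of 39 at uPCR 0.09); it is
  a package choice, not a published quantity;
* urinary creatinine lognormal (median 65 mg/dl, ln-sd 0.55, matching
  reported concentration tertiles near 36/65/128 mg/dl); concentrations are
  back-computed (uP = uPCR·uCr, uAlb = uACR·uCr/100), censored below the
  detection limits and reported at 0.1-unit assay precision;
* serum creatinine is made consistent with the patient's assigned GFR
  category by inverting the eGFR equation at a target eGFR drawn within the
  category band; the GFR mix follows the study's category distribution.

Randomness is split per patient (the per-patient stream is derived from the
run seed and the patient index), so patient k's data do not change when the
cohort grows and every output is bit-identical under a fixed seed.

The stability generator draws a true sample, then multiplies by lognormal
measurement noise per condition, with one shared freeze-thaw degradation
factor for the two day-3/4 measurements (they are consecutive assays of the
same degraded aliquot) and inflated protein noise (factor 6) for samples
below 3 mg/dl protein under any stored condition. That inflation is the
mechanism behind the observed pattern that trace-protein samples lose
between-day reproducibility while concentrated samples track the identity
line.

Deliberately not emulated: comorbidity structure, dipstick grades,
longitudinal eGFR trajectories beyond what eligibility needs, any
systematic storage *bias* (only variance inflation), and heavy-tailed assay
failures. Tests passing on these cohorts therefore show the pipeline is
correct and well-calibrated under a lognormal, correctly specified world;
they do not show the clinical conclusions transfer to any particular
laboratory, where the calibration should be re-fitted.

## Numerical choices and degenerate inputs

Quantiles are type 7 everywhere. Bin membership rounds half up through
`round()`'s banker's rounding on the label grid — at 0.01 resolution this
affects only exact midpoints, which assay-rounded data do not produce.
Segment intervals are closed on the left, `[lo, hi)`, with the domain's top
end inclusive. A rank-deficient spline design (an empty segment) is an
error naming the segment rather than a silent drop. Exact-fit models (RSS
numerically zero) report a slope change of 0 with p = 1 instead of 0/0.
Single-class ROC inputs are errors at the operation level and flagged rows
at the table level, so one degenerate subgroup does not abort a report.
`classify_albuminuria_patient` requires exactly three values; cohorts with
fewer visits drop the patient from patient-level tables.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes a laptop handles in seconds: the
default 303-patient cohort for end-to-end checks; 200 patients × 3 visits
for spline parameter recovery on binned medians; 700 patients at reduced
residual noise (sd ≈ 0.21) for AIC knot-count selection, where the four-knot
truth is reliably identified; about 10⁵ visits for Monte-Carlo convergence
of binned medians onto the truth curve; and 500 stability samples for the
low-protein correlation-degradation pattern. One caveat is recorded here
deliberately: at 200 × 3 the outermost spline segments (below the 5th and
above the 95th percentile knot) rest on one and a handful of occupied bins
respectively, so their slopes are not estimable to ±0.2 at that sample size
— the corresponding acceptance check fails honestly, and the interior
segments carry the scientific content.

## Known limitations

The calibration predicts the *median* uACR, not an individual's value; the
spread around the median is wide at low uPCR, which is precisely why the
cutoff analysis works on ROC curves rather than on the inverted
calibration alone. DeLong comparisons across overlapping subgroup tables
are not multiplicity-adjusted, matching common practice in this table
style. The per-measurement pooling ignores within-patient correlation, so
its confidence statements are anti-conservative by design fidelity. The
external-equation hook (a registry entry with someone else's coefficients)
is provided but no external coefficient set is bundled, since none is
available in a citable printed form here.
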