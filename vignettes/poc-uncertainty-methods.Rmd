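---
title: "Determining POC concentrations and their uncertainty budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining POC concentrations and their uncertainty budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocbudget)
```

## The measurement model

A POC determination from a bottle sample proceeds through four coupled
measurements, and `pocbudget` models each of them.

**Calibration.** Each CHN run is calibrated with pre-weighed acetanilide
standards; `fit_calibration()` fits `M = m x + b` by iteratively reweighted
least squares with bisquare weights. Robustness matters because a single
mis-weighed or mis-combusted standard would otherwise tilt the line for the
whole run. The intercept is tested and, when not significant at the 5% level,
the model is refitted through the origin — a single refit, not an iterated
search, so the reported model is one of exactly two candidate forms. The
residual scale `sigma_res` is the same percentile robust SD used everywhere
else in the package (half the P84–P16 distance), so one outlying standard
cannot inflate the prediction intervals either. Whether intercept
significance should be judged before or after robust reweighting is not
determined by the method description we follow; we test it on the robust
fit, which is the model actually reported.

Mass uncertainty uses a 68% *prediction* interval rather than a confidence
interval: each filter is a single future observation from the calibration
line, so the interval must include the residual scatter term (the leading 1
under the square root), not only the coefficient uncertainty. The 68% level
makes `sigma_M` directly comparable to a one-standard-deviation uncertainty.

**Run stability.** The stability standards interleaved with the filters
re-estimate the calibration mid-run. `detect_unstable_run()` compares the
two coefficient sets with Welch t-tests at `alpha = 0.05` (a declared
default; the field practice is a judgment call). Two implementation details
were forced by simulation rather than taste:

* both sets must be fitted *with* an intercept before comparing slopes — if
  one set prunes its intercept and the other does not, the pruned fit
  absorbs the intercept into its slope and a perfectly stable run looks
  drifted;
* the coefficient variances must be heteroscedasticity-consistent (HC3).
  Combustion noise grows with the carbon load, and with 8–19 standards per
  set the homoscedastic SEs are small enough to push the false-alarm rate
  from the nominal 5% to above 20%. With HC3 the simulated null is almost
  exactly nominal.

**Blank correction.** `blank_correct()` subtracts the run's capsule mean and
the acidification increment (desiccator acidified-blank mean minus run
non-acidified mean) from both filters of a pair. Because the paired filters
share one desiccator and one run, the corrections cancel in the difference
and the POC mass reduces to `M_uPOC − M_aDOC`; the function enforces the
pairing and the tests verify the cancellation to machine precision. Negative
corrected masses are kept and flagged — clipping at zero would bias every
median computed downstream.

**Duplicates.** The whole-dataset relative uncertainty `sigma_r` is the
robust SD of the relative duplicate differences per zone. It is a
*whole-dataset* scalar by design: with one duplicate pair per station there
is no information for per-sample spread. Percentiles interpolate linearly
between order statistics (the estimator's bias at n of a few dozen pairs is
far below its sampling noise either way). Pairs from unstable runs are
excluded so that two bad calibrations do not inflate the cruise-wide
precision; pairs whose mean concentration is non-positive have no meaningful
relative difference and are dropped with a warning.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| zone boundary | 200 | m | operational productive/mesopelagic split |
| `sigma_vn` | 0.010 | L | half a graduation mark of the measuring cylinder, per bottle |
| prediction level | 68% | — | matches a one-sigma uncertainty |
| intercept / stability alpha | 0.05 | — | conventional significance levels |
| detection quantile | 0.95 | — | IUPAC/ISO one-tailed convention |
| `residual_mode` | linear | — | see below |

The unquantified budget share is reported under two conventions: `linear`
(1 − Σu, the arithmetic used in budget tables of this kind) and `variance`
(√max(0, 1 − Σu²), the propagation-consistent form). Both columns are always
present; `linear` is the default headline because the shares are read as
fractions of the uncertainty, not of the variance. For detection limits the
ordinary (non-robust) SD of the pooled capsules is used — the convention for
blank statistics — and all capsules from all runs are pooled.

## What the synthetic cruise emulates

`synthetic_config()` encodes the study conditions the pipeline is meant for:
65 stations along a meridional Atlantic transect, six depths in the upper
500 m, one duplicate pair per station, filtered volumes of 1–8 L chosen by an
expected-concentration rule in 2.2 L bottles, 16 CHN runs with 11
calibration standards (5–300 µg) plus interleaved stability standards,
capsule blanks near 2 µg, clean filter blanks near 3 µg, acid-fumed blanks
near 4 µg, and true relative duplicate noise of 12% (productive) and 35%
(mesopelagic). The POC field is `22·exp(−z/130 m) + 5.5` mg/m³ with
lognormal station-to-station spread — a deliberately minimal profile that
reproduces zone medians near 19 and 7 mg/m³ without claiming any
oceanography. Two runs drift their sensitivity by 15% mid-run, which the
stability test must catch; the drift is kept mild so that the pooled
calibration stays nearly unbiased, consistent with drifted runs that add
scatter rather than bias.

Carbon on the lower filter is `2 µg + 0.09 × M_POC` plus 2 µg of scatter.
The coupling term reproduces the positive aDOC–POC correlation seen in
stacked-filter data (interpreted as particle leakage through the upper
filter); with these values the generated productive-zone correlation is
about 0.85 and aDOC/uPOC mass ratios sit near 10–13%. Instrument noise is
`1 + 0.012·x` response units (≈0.5 µg at zero load): the proportional term
makes standards residuals ≈2 µg while keeping capsule-blank scatter ≈1 µg,
both of which the additive-only model cannot do simultaneously. Blank carbon
has between-run and within-run components (new combustion tube and capsule
batch per run), so acidified blanks within one desiccator agree to a few
tenths of a µg while cruise-wide blank spread is ≈1 µg.

What the generator does **not** emulate: particle patchiness with
non-Gaussian tails, operator effects, storage contamination drift, volume
mis-recording beyond Gaussian per-bottle error, or any spatial covariance.
Passing tests therefore show that the *estimators* are correct and
calibrated under the stated noise model — not that real cruises are this
well behaved. Duplicate noise is multiplicative, `C·(1 + ε)` with Gaussian
ε per zone, because observed duplicate differences scale with concentration
while relative differences do not; at `sigma_r = 0.35` the ratio
`Δ/D̄` is slightly heavy-tailed and the percentile estimator recovers the
truth with a ~3% positive bias, well inside its sampling noise.

## Numerical choices and degenerate inputs

* Exact (noise-free) calibrations degenerate the IRLS scale estimate, so the
  fitter falls back to OLS when the OLS residual SD is below `1e-9` of the
  mass scale; residuals, `sigma_res`, and all prediction uncertainties are
  then exactly zero, and coefficient comparisons switch to direct equality
  at a relative `1e-8`.
* `predict_mass()` warns (but proceeds) outside the standards' response
  range — extrapolation is a data-quality signal, not an error.
* Eq.-15-style propagation clamps its quadratic form at zero against
  rounding; the mass correlation `r` is estimated within each run and falls
  back to the pooled cross-run value (with a message) when a run has fewer
  than three pairs.
* Samples below the detection limit, with negative masses, or with undefined
  budgets (`sigma_C ≤ 0`) are flagged and retained.
* Ties in duplicate linkage (station + depth) are broken by record order.

## A known limitation of the budget model

The calibration component propagates the two prediction-interval
uncertainties with a correlation term estimated from the *masses* within a
run. When aDOC mass is strongly coupled to POC mass, that correlation
(≈0.9 in coupled synthetic data) overstates the correlation of the
*prediction errors* (≈0 for independent combustions), and `sigma_C(M)` can
cancel to nearly zero. The budget-closure validation therefore runs the
generator with the aDOC–POC coupling switched off, isolating measurement
noise; under those conditions the modelled components recover ≥ 90% of the
experimental variance (slightly over 100% is expected, since the
prediction-interval factor exceeds one). On coupled data — synthetic or real
— the calibration share should be read as a lower bound.

## Problem sizes

The validation suite uses cruises of 10–65 stations, recovery experiments of
200 replicates × 500 duplicate pairs per true `sigma_r`, a one-million-draw
Gaussian check of the robust SD, and 50 random regression designs for the
prediction-interval oracle; the complete suite runs in about a minute on one
core.
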