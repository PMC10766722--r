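---
title: "Quantifying allergenic food proteins by multiplexed MRM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allergenic food proteins by multiplexed MRM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allerquant)
```

## The measurement problem

Trace amounts of allergenic foods (milk, egg, peanut, soybean, hazelnut,
almond) in a processed matrix such as chocolate are quantified by targeted
LC-MS: for each allergen a small set of proteotypic tryptic peptides is
monitored by multiple reaction monitoring (MRM), each in a native
("light") form and as an isotopically labelled ("heavy") internal
standard spiked at a fixed concentration. The analytical signal is the
light/heavy peak-area ratio, which cancels most of the run-to-run
instrumental and clean-up variability.

Risk management, however, is framed in *total allergenic food protein*
(TAFP): reference doses are milligrams of the allergenic food's total
protein, not femtomoles of one peptide. `allerquant` implements the whole
post-acquisition chain from peak-area tables to TAFP results with
measurement uncertainty, plus a synthetic-data generator that produces
every input the chain consumes.

## Calibration and sensitivity

Matrix-matched calibration curves (MMCC; calibrants spiked into blank
matrix digest) and standard curves (SCC; calibrants in buffer) are fitted
by unweighted ordinary least squares of the ratio $y$ on the
concentration $x$ (fmol/µL), with replicate ratios entering as individual
observations. No weighting is applied; heteroscedasticity over the
two-decade range is handled, as in common practice, by computing
detection limits on a restricted low-concentration subset
(`range_limit`, default use: ≤ 5 fmol/µL).

The matrix effect is tested in two stages on the quantitative marker of
each allergen:

1. a one-tailed Fisher–Snedecor screen of the regression variances,
   $F = s^2_{max}/s^2_{min}$ at $\alpha = 0.01$ with
   $(n_1-2,\,n_2-2)$ degrees of freedom;
2. if poolable, a two-tailed Student test of the slopes with the
   df-weighted pooled residual variance,
   $t = |b_1-b_2| \big/ \sqrt{s^2_p\,(1/S_{xx,1} + 1/S_{xx,2})}$ on
   $n_1+n_2-4$ df.

When the F screen fails, the t branch is reported *not applicable* — no
Welch fallback is silently substituted, because the pooled-variance
procedure is the method's defined behaviour. Note that when the ratio
noise is proportional to the signal, two curves of different slope have
genuinely different residual variances, and the screen can legitimately
refuse pooling; the screen is exactly calibrated under homoscedastic
noise.

Detection and quantification limits use
$\mathrm{LOD} = 3\,SD/b$, $\mathrm{LOQ} = 10\,SD/b$ with three SD
estimators: the intercept SD (default; the most conservative
calibration-based choice that is still realistic), the residual SD
(typically an overestimate, since it integrates variance over the whole
line), and the SD of ≥ 5 replicate ratios at the lowest detected point.
LOQ/LOD ≡ 10/3 by construction for a given estimator.

## Reporting-unit conversion and conversion factors

The interpolated peptide concentration $x_{0,\mathrm{peptide}} =
(\bar y_0 - a)/b$ converts to TAFP as

$$x_{0,\mathrm{TAFP}}\ [\mu g/g] \;=\; x_{0,\mathrm{peptide}}\ [fmol/\mu L]
\times \frac{cMM}{cCF} \times m \times d,$$

with $m = 10^{-5}$ (1:10 matrix-to-solvent extraction plus SI prefixes)
and $d = 1.33$ (digestion dilution). $cMM$ is the *centered molar mass*
of the parent protein — midpoint of the min–max range over sequenced
isoforms/variants — and $cCF$ the *centered conversion factor*, the
fraction of the ingredient's total protein contributed by the marker's
parent protein(s), estimated from discovery proteomics: per replicate,
the summed intensity of marker-carrying accessions (each gated on ≥ 1
unique peptide) over the summed intensity of all identified proteins.
Both centered quantities carry rectangular-distribution uncertainties,
$u = \text{half-range}/\sqrt{3}$.

Two semantics of "average" coexist in the field for the CF: the plain
mean of replicates and the midpoint of their range. The midpoint is
implemented as the defining value because it is the formula-level
companion of the half-range uncertainty; the plain mean is reported
alongside for transparency (`centered_estimate()$mean`). Replicates in
which no marker accession passes the unique-peptide gate are excluded
with a warning rather than scored as CF = 0, which would be a gross
downward bias.

The packaged panel ships the experimentally established conversion
factors where they are published (milk caseinate 0.374 ± 0.009, milk whey
0.193 ± 0.002, egg-white ovalbumin 0.468 ± 0.003, peanut Ara h 3
0.695 ± 0.006) and documented representative defaults elsewhere; the
molar-mass isoform ranges are likewise representative synthetic defaults.
Users with their own discovery data should replace both via
`estimate_cf()` and `centered_molar_mass()`.

For compliance reporting only, an entry may carry a `compliance_cf`
(egg white: 0.54, the theoretical ovalbumin share of egg-white protein)
used when the dose scheme refers to a different protein basis; sample
quantification never uses it.

## Decision rules

An allergen is *detected* when at least two transitions of at least two
of its marker peptides interpolate at or above their peptide-specific
LODs (inclusive comparisons; a single-marker allergen requires an
explicit override because the rule degenerates). It is *quantified* when
additionally the quantitative marker's concentration is at or above its
LOQ. Negative interpolations are floored at zero and can never qualify
as evidence. Averaging of replicate ratios across groups (samples, days,
analysts) is gated on a one-way ANOVA poolability check at 95%
confidence, and quantification refuses to proceed on non-poolable groups
unless forced (forced sub-LOQ values are flagged `"<LOQ"`).

Whether the quantitative marker's own transitions count toward the
two-peptide requirement is ambiguous in common phrasing of the rule; it
is implemented as *any* two peptides including the QTM.

## The five-contributor uncertainty budget

For a quantified content $x_0$ the combined standard uncertainty is the
first-order propagation of five terms:

$$u_{x_0} = x_0 \sqrt{
 \left(\tfrac{u_{PR}}{x_0}\right)^2 +
 \left(\tfrac{u_{SS}}{x_{SS}}\right)^2 +
 \left(\tfrac{u_{RL}}{x_0}\right)^2 +
 \left(\tfrac{u_{MM}}{cMM}\right)^2 +
 \left(\tfrac{u_{CF}}{cCF}\right)^2},\qquad
U_{x_0} = k\,u_{x_0},\ k = 2.$$

* $u_{PR}$: SD of the replicate determinations (technical and biological
  pooled, after the ANOVA gate) divided by $\sqrt 3$;
* $u_{SS}/x_{SS}$: the stock-solution term is a pure relative
  contribution — the stock concentration cancels from the ratio — so it
  is carried as $0.30/\sqrt 3$ (conservative upper end of the quoted
  25–30% amino-acid-analysis precision);
* $u_{RL} = \dfrac{S_{y/x}}{b}\sqrt{\dfrac1p + \dfrac1n +
  \dfrac{(\bar y_0 - \bar y)^2}{b^2 S_{xx}}}$ with
  $S_{xx} = \sum_i (x_i - \bar x)^2$ (a printed form of this denominator
  circulates with a typographical garbling; the standard
  interpolation-uncertainty form is used);
* $u_{MM}$, $u_{CF}$: the rectangular half-range terms above.

All five terms are assembled on the peptide-concentration scale, where
they are dimensionless after division; the TAFP conversion is linear, so
value and uncertainty convert identically. The first-order combination
was verified against rectangular/Gaussian Monte-Carlo propagation; with
individual relative contributions up to ~8% the two agree within 2%,
which is the documented validity range of the closed form (the stock
term, at 17% relative, is itself exact in the propagation since it
enters multiplicatively).

## Precision, stability and recovery

*Repeatability* (one day, $b$ biological × $t$ technical replicates)
uses the one-way random-effects method of moments:
$\hat\sigma^2_{IA} = MS_{within}$,
$\hat\sigma^2_{SP} = \max\!\big(0, (MS_{between}-MS_{within})/t\big)$,
with the total CV% on the grand mean of the determined content (fmol/µL)
and component weights as shares of the total variance.

*Intermediate precision* first averages technical replicates to
prepared-sample means (so the reported SP component absorbs the small
residual instrumental share, matching the convention of quoting weights
over SP/DA/A only), then decomposes a days × analysts crossed layout
with samples nested in cells by expected mean squares. Negative
method-of-moments estimates are truncated to zero before weight
normalisation — standard practice for balanced designs. A factor absent
from the design is reported `"nt"` and weights renormalise. Method of
moments was chosen over REML deliberately: the designs are small and
balanced, the estimator is closed-form and reproducible without an
optimizer, and its unbiasedness (before truncation) is what the
parameter-recovery tests exercise. Unbalanced layouts are reduced to the
largest balanced subset with a warning rather than silently reweighted.

Note that the per-dataset *weights* are a nonlinear function of two
noisy mean squares; at 3 × 3 their single-experiment values scatter
widely around the generating shares, so recovery is assessed on variance
components averaged over replicated simulations, where the
method-of-moments estimators are unbiased.

*Stability* compares the reference day against each later day with
two-sample pooled t-tests at 5%; stable iff none is significant (with
one later day the familywise level equals the per-test level, which is
the configuration used for the calibration checks). *Recovery* is the
percent ratio of the contents determined in samples spiked before vs
after extraction/purification (SB/SA), both quantified through the MMCC.

## Compliance reporting

Per-gram limits convert to per-portion doses as
$\mu g/g \times 25\,g / 1000$ (25 g is a standard chocolate-bar
portion) and are compared with the packaged reference-dose grid (VITAL
3.0, German, Dutch and Belgian recommendations, FAO/WHO consultation);
schemes without an issued dose yield no verdict. The published
per-portion column is numerically the per-gram *LOD* column times the
portion factor, so the LOD basis is the default (selectable); rendered
per-portion values use one significant figure, and all rounding happens
only at the reporting layer.

## The synthetic-data generator

The generator reproduces the *statistical structure* the analysis
assumes, under the study's stated designs:

* **Calibration**: ten points at 0, 0.5, 1, 1.5, 2, 3, 5, 10, 25,
  50 fmol/µL including the blank, heavy standard at 25 fmol/µL, three
  technical replicates. Noise acts on the ratio (Gaussian, SD
  $\sqrt{(0.05\,\mu)^2 + (5\cdot10^{-4})^2}$ — a 5% relative component
  with an absolute floor), because the L/H normalisation removes most
  area-scale variability; heavy areas are drawn around a constant and
  light areas derived, so that normalisation is structurally present.
  A small true blank background (intercept 0.002) keeps the noise model
  honest near zero (ratios are truncated at 0, and a zero intercept
  would make the truncation bite at the blank). The default true slopes
  are anchored at the published matrix-matched sensitivities
  (`default_true_slopes()`); the matrix curve is attenuated by 0.85
  relative to the standard curve by default.
* **Incurred samples**: levels 2, 4, 10, 40 µg TAFP/g; the expected
  marker concentration is the TAFP level pushed backwards through the
  conversion equation. Sample-preparation, day and analyst effects are
  multiplicative log-normal (SDs 0.05, 0.05, 0.02 on the log scale) and
  shared by all markers of a prepared sample; instrumental error is
  additive Gaussian on the ratio (SD 0.004). This mixed structure makes
  the instrumental term dominate near the detection limit and
  preparation dominate at high content — the pattern the validation
  data display — and it is a stand-in: no distributional form for the
  real noise is established. All markers of an allergen are simulated at
  the same molar concentration (equimolar release), which ignores
  QLM-specific digestion efficiency.
* **Discovery tables**: per replicate, protein intensities proportional
  to true relative abundances with mean-corrected log-normal noise
  (CV 10%, 6 replicates); the packaged profile is a stylised milk
  protein profile whose marker accessions sum to 0.374.
* **Recovery pairs**: SB expected content = true recovery × SA expected
  content; both arms share the run (day/analyst effects zeroed), so the
  SB/SA ratio estimates recovery without a run-offset nuisance.

A single master seed fans out to per-dataset substreams by a stable
label hash (`substream_seed()`), so enlarging one design never perturbs
another dataset's stream, and all arithmetic stays below $2^{31}$.

What passing tests on this generator do **not** show: robustness to
chromatographic interferences, retention-time drift, non-Gaussian
heavy-tailed noise, digestion-efficiency differences between markers,
matrix-to-matrix CF transfer, or the natural variability of ingredient
protein profiles (the CF uncertainty covers only the analytical
replication, a known limitation of experimentally derived CFs).

## Numerical choices and test scales

* OLS via `stats::lm`; fits require ≥ 3 distinct levels and error on
  constant designs. Fit equality to an independent normal-equations
  oracle is verified to 1e-10 relative.
* LOD parameter recovery is checked under homoscedastic noise against
  the exact Gaussian sampling expectation (including the small-sample
  $c_4$ factor on the residual SD); under the heteroscedastic default
  only the slope is checked against truth, because "the" LOD of a
  heteroscedastic generator has no closed form the estimator targets.
* Degenerate inputs: zero heavy areas are flagged records, not zeros;
  constant stability data compare trivially (identical → stable,
  shifted → unstable); single-replicate budgets set $u_{PR}=0$ with a
  warning; single-basis centered estimates set $u = 0$ with a warning.
* Simulation scales used by the test suite (chosen to make Monte-Carlo
  error comfortably smaller than the tolerances they support): 2000
  null replications for the type-I calibrations, 400–500 replications
  for parameter recovery, 10^6 draws per Monte-Carlo propagation
  budget, 20 random budgets, 200 random OLS instances.
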