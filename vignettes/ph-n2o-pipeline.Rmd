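---
title: "Methods: pH control of N2O emission factors, from field records to peak estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pH control of N2O emission factors, from field records to peak estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2oph)
```

## The scientific problem

Nitrogen fertilization drives N₂O emissions, but the fraction of applied
N emitted — the emission factor (EF) — varies widely between sites, and
soil pH is a leading candidate for explaining that variation. The
mechanistic expectation is not monotone. Denitrification produces N₂O
(via the nitrite reductases encoded by *nirK* and *nirS*) and consumes
it (via the N₂O reductase encoded by *nosZ*); N₂O reductase is the more
acid-sensitive enzyme, so acidity raises the N₂O/(N₂O+N₂) product ratio,
while strong acidity suppresses the overall activity of nitrifiers and
denitrifiers alike. The net result is a hump: EFs should peak in
moderately acidic soil and fall away on both sides. This package
implements the quantitative machinery for testing that expectation on
compiled field data, on functional-gene surveys, and on laboratory
incubations.

## The estimation procedure

### Emission factors and weighting

Each observation pairs a fertilized plot with an unfertilized control:
`EF(%) = 100 (E_N − E_O)/N`. Negative EFs arise when the control emits
more than the fertilized plot; they are retained in every analysis and
merely counted, since excluding them would bias the low tail upward.

Raw ("coarse") EF observations over-represent the pH increments where
many experiments happen to have been done. The averaging pathway
therefore bins observations into half-open 0.1-pH intervals
`[x, x+0.1)` and gives every increment one replicate-weighted mean,
`M = Σ Y_i W_i / Σ W_i` with `W_i = n_i/o` (replicates over bin
occupancy). Within a bin the occupancy `o` cancels from `M`; its role is
to make the weights comparable across bins when bin tables are combined.
Observations lacking a replicate count receive the neutral weight `1/o`
and a flag — the weighting rule is undefined without `n`, and silent
exclusion would discard otherwise valid EFs.

Both pathways are fitted and reported side by side: the coarse fit
answers "what does the raw compilation show", the averaged fit answers
"what does the pH axis show when every increment counts equally". Both
are kept because they answer different questions; disagreement between
their peaks is itself informative about sampling imbalance.

### Model competition and the peak

Degree-1 and degree-2 polynomials are fitted by (optionally weighted)
least squares via `stats::lm`. Model choice uses the small-sample
corrected AICc with `k = p + 2` parameters for a degree-`p` fit — the
Gaussian error variance is counted, which matters because the published
convention of common model-selection tooling does the same and the
correction term depends on `k`. A difference above 2 selects the
lower-AICc model; anything closer is treated as a statistical tie and
resolved to the linear model, since claiming a pH optimum requires
positive evidence for curvature. A perfect fit (residual sum of squares
exactly zero) is assigned AICc −∞, which keeps the selection rule
well-defined on noise-free data: a perfectly linear dataset still
chooses the line, and a perfectly quadratic one the parabola.

The reported peak is the vertex `pH* = −c₁/(2c₂)` of a concave
quadratic. Convex fits have no interior maximum and return nothing;
vertices outside the observed pH range are flagged, because a vertex
extrapolated beyond the data is an artefact of the functional form, not
a measured optimum. Peaks are printed to one decimal in summaries (the
precision at which pH is meaningfully reported) with full precision kept
in machine output.

### Harmonization choices

* **pH medium.** Salt-suspension pH (CaCl₂, KCl) reads lower than
  water-suspension pH. The package applies per-medium affine maps with
  defaults of +0.6 (CaCl₂) and +1.0 (KCl) at slope 1 — typical offsets
  from pedotransfer comparisons — and flags every converted value.
  These are deliberately configuration, not constants: users analysing
  their own soils should calibrate the coefficients, and every report
  echoes the table used.
* **Unknown medium** is assumed to be water, with a warning; this is the
  only defensible default since water is the dominant method, but the
  assumption is surfaced rather than silent.
* **Climate zones** are absolute-latitude bands: tropical `[0, 23.4]`,
  subtropical `(23.4, 35.0]`, temperate `(35.0, 90]`. The boundary
  values are assigned to the closed upper edge of the lower band, a
  convention chosen once so the bands partition the axis.
* **Acidity classes** follow the ten-class USDA soil-reaction table.
  Its printed edges are closed intervals at one-decimal resolution, so
  inputs are rounded to one decimal before lookup; pH above 9.0 falls
  outside the published table and is labelled strongly alkaline with an
  out-of-table flag.

### Gene abundances

Published qPCR abundances mostly circulate as log₁₀ values. Averaging
logs gives a geometric mean, which systematically understates the
arithmetic mean abundance of a pH increment; the pipeline therefore
back-transforms, averages copies g⁻¹ on the linear scale within each
bin, and re-logs. Jensen's inequality guarantees the linear-then-log
mean is never below the mean of logs, and the test suite asserts this on
random inputs.

The (nirK+nirS)/nosZI ratio is computed per sample, only when all three
genes were quantified in that sample; *nosZII* records are stored and
counted but never enter the ratio, because clade II quantifications
paired with flux data are too scarce in field compilations to support
one. Global-compilation ratio fits use log₁₀(ratio) as the response;
field-experiment fits use the linear-scale ratio — both modes exist and
every report names the one used.

### Incubation calculators

The headspace flux formula converts a ppm change in a closed bottle to a
soil-mass-specific N flux. Two conventions had to be fixed: the
accumulation interval divisor (the formula as usually printed has no
explicit time term) and the identity of the gas density. The package
divides by the sealed-accumulation interval — 6 h by default, or 1 h
when the input is already a regression slope in ppm h⁻¹ — and uses the
N₂O density at standard state (1.964 kg m⁻³) with the molecular N
fraction 28/44 converting gas mass to N mass. All three are arguments,
defaulted and echoed, not buried constants. Headspace volume is taken as
the bottle volume; the displacement of the soil slurry is not modelled,
a documented simplification that biases rates slightly upward for large
soil volumes.

Potential denitrification activity (PDA) is the slope-rate of an
acetylene-amended bottle — acetylene blocks N₂O reductase, so
accumulated N₂O measures total denitrification — reported in
mg N kg⁻¹ h⁻¹, the conventional PDA unit. The product ratio divides the
no-acetylene rate (net N₂O) by the acetylene rate (N₂O+N₂). Noise can
push the quotient outside [0, 1]; the reported ratio is clamped with a
flag, while the raw quotient is preserved. Negative accumulation slopes
(net N₂O uptake) are reported as negative rates, never zeroed — clamping
is a property of the ratio, not of fluxes.

## What the synthetic generators emulate — and what they do not

The generators exist so that every stage has a dataset with known ground
truth. Their defaults define one fixed set of study-like conditions:

* **Field dataset**: 400 studies × 5 observations = 2000 rows. Soil pH
  from a three-component normal mixture, means 5.0/6.5/8.0, sds
  0.9/0.7/0.6, weights 0.3/0.5/0.2, redrawn (not clamped) into
  [2.8, 9.7]; this puts roughly 55% of observations at pH 5.5–7.5 and
  populates the full range the way compiled datasets do. The true EF
  curve is `−2.6 + 1.2 pH − 0.1 pH²` — peak at exactly pH 6.0, peak EF
  1.0% — with additive Gaussian noise (sd 0.2%). The noise level is set
  so that the bin-averaged pipeline estimates the peak with a
  seed-to-seed standard deviation of about 0.03 pH units at n = 2000,
  i.e. so the generator's defining recovery property (peak within ±0.1)
  holds with a three-sigma margin. Replicates are uniform on 3–6 per
  study; N rates uniform on 50–600 kg N ha⁻¹; control emissions
  lognormal (median 0.5 kg N ha⁻¹). The fertilized emission is
  constructed as `E_O + EF/100 × N`, so at zero noise `compute_ef`
  inverts the generator exactly.
* **Gene dataset**: 500 samples; log₁₀ abundances quadratic in pH using
  the published-scale coarse curves for *nirK* and *nirS* and a flat
  nosZI response at 7.3 log copies, noise sd 0.3 log units; flux linear
  in the true log ratio (intercept 40, slope 25 µg N m⁻² h⁻¹) plus
  noise.
* **Incubation pairs**: 70 samples on a pH 4.7–8.0 gradient; total
  denitrification from a concave quadratic peaking near pH 6.7
  (converted mg → µg), product ratio from the line `1.265 − 0.082 pH`
  (validated to stay within [0, 1] over the range before any sampling);
  ppm series built by inverting the flux formula, with 2% multiplicative
  reading noise.

What they deliberately do **not** emulate: real compiled EF data are far
noisier than the default generator (raw-observation fits on compilations
explain only a few percent of variance), have study-level clustering and
heteroscedastic errors, and their pH coverage is uneven in ways a smooth
mixture cannot reproduce. Passing the ±0.1 recovery test therefore
demonstrates that the pipeline machinery is unbiased and correctly
plumbed — it does **not** imply that a real-world compilation determines
the peak to ±0.1. Observations are exchangeable within study (no spatial
or temporal autocorrelation), and the generators never call pipeline
code, keeping oracle and subject independent.

## Numerical choices

* **Bin edges.** Bins are `[anchor + k·w, anchor + (k+1)·w)` with the
  index computed as `floor(round((x − anchor)/w, 9))`: the 9-decimal
  pre-round prevents values printed exactly at an edge (5.7 with width
  0.1) from being pushed into the lower bin by binary representation.
* **Zero-residual snapping.** A residual sum of squares below 1e−20 of
  the response's scale is treated as exactly zero, which routes
  perfect fits into the −∞-AICc branch instead of amplifying
  floating-point noise into arbitrary selections.
* **Rank checks.** Fits require at least `degree + 2` points and
  `degree + 1` distinct x values; collinear designs error with a named
  condition instead of returning NA coefficients.
* **pH conversion clamping.** Converted pH is kept inside (0, 14) by a
  1e−6 margin; the conversion is affine with positive slope, hence
  monotone.
* **Determinism.** Generators are functions of (config, seed) only; the
  same configuration yields byte-identical tables, which the suite
  asserts.

## Design decisions that were genuinely open

* **Occupancy in the weight rule** counts observations per bin, not
  studies: the rule's own definition refers to observations in the
  increment, and per-study collapsing is left to users who want it.
* **Averaged-fit weighting** is unweighted by default across bins
  (each increment equal — the stated purpose of averaging), with a
  `weight_bins` switch; note that the within-bin weight sum `Σ n_i/o`
  is approximately the mean replicate count and so nearly constant
  across bins, which is why the switch changes little in practice.
* **Tie-breaking to the simpler model** under the AICc threshold:
  claiming curvature, and hence a pH optimum, is the stronger claim and
  should carry the burden of evidence.
* **Duplicates are kept**: identical (study, pH, rate) rows are treated
  as distinct observations; deduplication policy belongs to data
  curation, not to the estimator.
* **Per-row medium conversion**: each observation is converted according
  to its own reported medium rather than a single global rule.

## Problem sizes in the shipped checks

The package's own test suite runs the full pipeline at the default
n = 2000 field dataset, 200-replicate Monte-Carlo loops for peak
recovery, slope recovery and confidence-band coverage, and 10-point
instances for the algebraic oracles — sizes chosen so the whole suite
completes in well under a minute on a laptop while leaving the
Monte-Carlo assertions statistically meaningful.

## Known limitations

* The pH-conversion defaults are generic offsets; publication-grade use
  requires locally calibrated coefficients (they are arguments
  everywhere).
* No random-effects meta-analytic variance model: the weighting is the
  fixed replicate rule, so between-study heterogeneity is not
  propagated into peak uncertainty.
* No bootstrap or profile confidence interval on the vertex; the
  confidence band covers the mean response, not the arg-max.
* Emission periods are stored as given: if studies mix seasonal and
  annual cumulative emissions, harmonizing them is the user's task.
* The incubation calculators assume ideal-gas headspace behaviour and
  ignore dissolved N₂O (no Bunsen-coefficient correction) and soil
  volume displacement.
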