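---
title: "Dual classification of metabolic syndrome from FTIR plasma spectra: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual classification of metabolic syndrome from FTIR plasma spectra: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsir)
```

`metsir` implements a dual strategy for discriminating metabolic syndrome
(MetS) from mid-infrared plasma spectra: a *discriminant* route (SELECT
variable selection followed by linear discriminant analysis) that always
assigns a sample to one of the two groups, and a *class-modelling* route
(SIMCA) that builds an independent model per class and can also declare a
sample a member of both classes or of neither. This vignette explains the
models, the tunable parameters and their defaults, the synthetic data the
package tests itself on, and the numerical choices made where the design
was genuinely open.

## The clinical rule engine

MetS is labelled by the NCEP-ATP-III rule: at least `n_required = 3` of the
risk-factor criteria must be met. Four criteria are computable from the
five measured parameters (waist circumference is not part of the table, a
common situation in registries):

| criterion | rule | units |
|---|---|---|
| triglycerides | TGL ≥ 150 (inclusive) | mg/dL |
| HDL cholesterol | HDL < 50 (women) / < 40 (men) | mg/dL |
| blood pressure | SP > 130 **or** DP > 85 (one criterion) | mmHg |
| fasting glucose | GLU > 110 | mg/dL |

Blood pressure is deliberately a single criterion: the rule lists five risk
factors of which elevated blood pressure is one, so counting the systolic
and diastolic halves separately would inflate the count to six. The strict
(`>`) cut-offs for pressure and glucose versus the inclusive (`≥`) cut-off
for triglycerides follow the rule's own wording; `mets_thresholds()` makes
both the cut-offs and the inclusivity configurable, and HDL for a subject
of unknown sex defaults to the conservative male cut-off.

## Preprocessing

The pipeline order is fixed: replicate averaging → Savitzky–Golay →
SNV → region restriction → mean centering.

* **Replicate averaging.** Spectra are acquired in triplicate; the mean
  spectrum per sample is taken *before* any other treatment, matching the
  acquisition protocol in which a mean spectrum is formed directly from
  the recorded replicates.
* **Savitzky–Golay** (`savitzky_golay()`): default window 9, polynomial
  order 2, derivative 0. The published analysis reports that smoothing
  plus SNV outperformed derivative pipelines but not the window used; 9/2
  is a conservative standard for ~1 cm⁻¹-spaced FTIR data that suppresses
  noise without flattening 5–10 cm⁻¹-wide bands. Filtering is applied
  separately within each contiguous uniform grid segment, never convolving
  across the gap between the two analysed regions, and errors if spacing
  within a segment deviates by more than 1e-6 cm⁻¹ (the filter assumes
  uniformity). Derivatives are with respect to wavenumber: since grids are
  stored descending, odd derivatives flip sign relative to the column
  index direction.
* **SNV** (`snv()`): per-spectrum centering and unit-variance scaling
  (n−1 denominator), removing offset and multiplicative scatter. A
  constant spectrum is an error naming the sample.
* **EMSC** (`emsc()`) is provided as an alternative scatter correction —
  regression on a reference spectrum plus a quadratic wavenumber baseline
  — with the training-set mean as the default reference (the method needs
  *some* reference and the data themselves are the only source).
* **Region restriction** keeps the analysed ranges, by default 1583–1050
  and 2973–2700 cm⁻¹ (838 points in total). Strong water absorption and
  noise make the rest of the mid-IR range uninformative for plasma.
* **Mean centering** (`mean_center()`) returns the means it used so test
  samples are always centered with *training* means.

## SELECT

SELECT ranks wavenumbers by iterating two steps on the training matrix:

1. score every remaining variable with the Fisher class-separation weight
   $w_j = (\bar x_{1j} - \bar x_{2j})^2 / (s_{1j}^2 + s_{2j}^2)$
   and pick the argmax (ties, a measure-zero event, break to the lowest
   column index so runs are deterministic);
2. replace every other variable by its residual after least-squares
   regression (with intercept) on the picked one, so variables correlated
   with what is already selected cannot be picked again for the same
   information.

The literature this algorithm family comes from does not print a single
canonical criterion; the Fisher-type weight above is the standard
class-separation choice and is stated here explicitly so results are
reproducible. Selection stops at `k_max` (default 20), at the
training-objects rule `k ≤ floor(n_train / 3)`, or optionally at a weight
floor (disabled by default). Orthogonalization keeps each column's mean, so
a variable with zero covariance against the picked one is genuinely
untouched. The residual-vs-intercept choice matters only for uncentered
input; on centered data the intercept is null and is kept for safety.

## LDA

`fit_lda()` is classic pooled-covariance two-class LDA. Priors are equal by
default — the chemometric convention, and with a 19/86 imbalance the
proportional alternative would let the majority class dominate the
boundary; proportional priors remain available. When the pooled covariance
is ill-conditioned (condition number above 1e10; the 20-variable spectral
model with 18 training samples in the smaller class is near-degenerate), a
ridge of `1e-8 × trace(S)/p` is added — small enough to leave
well-conditioned fits untouched. Leave-one-out cross-validation refits
everything per fold (means, covariance, ridge), so the held-out sample
never leaks into its own prediction; the suite verifies fold-for-fold
equality against a naive refit oracle and against an independent
implementation. `canonical_scores()` returns the one-dimensional
discriminant axis shifted so the decision threshold is 0, ready for the
class-separation histograms.

## NIPALS PCA and SIMCA

Principal components are computed by NIPALS with sequential deflation
(tolerance 1e-10 on the relative score change, at most 500 iterations per
component, sign fixed so the largest-magnitude loading element is
positive). NIPALS converges slowly when two eigenvalues nearly tie — for
trailing noise components this is harmless (any basis of the near-degenerate
subspace gives the same residuals) and is recorded in the model and
warned about rather than hidden. Exploratory PCA centers only (spectra are
already SNV-treated); the SIMCA inner PCA autoscales within each class.

A SIMCA class model for class $g$ with $A$ components on $p$ variables and
$n$ training samples defines

$$ s_0^2 = \frac{\sum_{ij} e_{ij}^2}{(n - A - 1)(p - A)}, \qquad
   s^2(x) = \frac{\sum_j e_j(x)^2}{p - A}, $$

and accepts a sample when its reduced distance $d = s(x)/s_0$ satisfies
$d^2 \le F_{1-\alpha}(p - A,\ (n - A - 1)(p - A))$ with $\alpha = 0.05$ —
the classic one-sided F-test on residual variance ("the distance to the
model is not significantly different from the class residual SD"). The
degrees of freedom use the $n - A - 1$ convention; the $n - A$ alternative
differs visibly only in very small classes, and fixing one convention
matters more than which one. New samples are always autoscaled with the
*class model's* center and scale, never their own.

Diagnostics:

* **Modelling power** $MP_j = 1 - s_j(\text{residual})/s_j(\text{total})$,
  clipped to [0, 1]; the total SD is 1 by autoscaling.
* **Discriminant power**
  $DP_j = \sqrt{\frac{SS_j(X_2|M_1) + SS_j(X_1|M_2)}{SS_j(X_1|M_1) + SS_j(X_2|M_2)}}$,
  ≈1 for a variable distributed identically in both classes, symmetric
  under class swap.
* **Interclass distance**: the same ratio aggregated over all variables
  and samples; exactly 1 for a class against itself, values above ~3 for
  well-separated classes.
* **Cooman coordinates**: each sample's pair of reduced distances plus the
  two critical distances. The "augmented distance" option additionally
  folds in score-space leverage (the Hotelling distance of the projected
  sample, rescaled so its own F-limit maps onto the residual critical
  distance, combined as $\sqrt{d_{\text{resid}}^2 + d_{\text{score}}^2}$).
  The augmented form is named but not defined in the source literature, so
  this package defines it explicitly and keeps the pure residual distance
  as the default.

The SIMCA spectral branch consumes the SELECT ranking truncated from 20 to
10 variables by recognition-guided removal: at each step the variable whose
removal maximises training recognition (own-class acceptance) is dropped,
preferring the lowest SELECT weight on ties, until ten remain. This
realises "the best recognition was achieved by ten of the twenty selected
variables" as a concrete, deterministic procedure.

## The synthetic generator

No patient data are distributed with, or downloadable for, this problem, so
`make_dataset()` generates the study conditions:

* **Design**: 19 MetS / 86 noMetS samples, spectra in triplicate on the
  838-point two-region grid. The grid allocates points to the two segments
  proportionally to their widths (554 + 284), which makes both segment
  spacings agree with the nominal common spacing 806/836 ≈ 0.964 cm⁻¹ to
  within 1e-3 — exact equality of the two spacings with integer point
  counts is arithmetically impossible, and anchoring the segment endpoints
  at the stated range limits was judged more important.
* **Clinical values**: per class and parameter, truncated normals with the
  published cohort mean, truncated to the published [min, max], with
  sd = (max − min)/4 — the only spread statistic recoverable from a
  min/max/mean summary that reproduces the reported box-plot spread
  qualitatively. Sex is Bernoulli(0.5); the cohort's sex distribution is
  not published.
* **Spectra**: sums of Gaussian bands (the simplest shape that exercises
  smoothing and SNV correctly) plus a per-spectrum linear baseline
  (offset sd 0.01, slope sd 1e-5 per cm⁻¹), a multiplicative scatter
  factor (sd 0.05) and iid noise (sd 0.005 absorbance) — the artefacts
  SNV/EMSC exist to remove. Ten *informative* bands sit at the
  discriminating band centers, linked to clinical variables in the
  direction of the published band assignments: CH₂/CH₃ lipid stretches
  (2860.22, 2948.94 cm⁻¹) to TGL, carbohydrate C–O bands (1108.98,
  1133.09 cm⁻¹) to GLU, amide-II protein bands (1557.40, 1562.22,
  1578.61 cm⁻¹) negatively to HDL. The remaining three centers (1423.36,
  1316.32, 1247.85 cm⁻¹) have no published metabolite link and are
  assigned to SP, DP and TGL so that all ten centers are informative, as
  the simulation design requires. Eight class-neutral background bands
  emulate the shared plasma matrix.
* **Effect size**: band amplitude = base + strength × (z + effect/2 × g),
  where z is the clinical value standardized by fixed population
  constants and g = ±1 the class sign. `effect_size` is therefore exactly
  the controlled between-class amplitude shift in units of its
  within-class SD; the clinical covariation adds a further small
  separation in the same direction. The strength of each clinical→band
  link is not identifiable from published material — these are tuning
  constants of the simulation, not estimates. The default `effect_size = 6`
  is the stated strong-signal regime under which the spectral branches are
  expected to classify perfectly.

What passing tests on these data do **not** show: performance on real
plasma spectra. The generator has no water-vapour/CO₂ artefacts (suppressed
instrumentally in the protocol), no Mie-type wavelength-dependent scatter,
no inter-patient covariance beyond the five clinical parameters, and
Gaussian rather than Voigt band shapes. Published per-dataset figures (PC1
explained variance of 50.46%/83.12%, the specific DP values, the interclass
distances 4.26/5.19) depend on the unavailable cohort and are therefore
*not* acceptance targets; the simulation reproduces their qualitative
structure (e.g. interclass distances well above 3, MP ≈ 1 for informative
bands) rather than their digits.

## Split, determinism and problem sizes

The 95/10 train/test split is stratified by class (how the original split
was drawn is unstated; stratification guarantees MetS samples in a
10-sample test set, without which external MetS rates are undefined) and is
drawn once per run and shared by all four branches. Every stochastic step —
generation, split — is governed by explicit integer seeds, and rerunning
with the same configuration is bit-identical.

The test suite sizes its simulations to make each property decisive but
cheap: oracle comparisons on matrices up to 50 × 50, coverage and null
checks at 500–1000 samples, parameter recovery at 1000 per class, and the
full pipeline at the study's own 105 × 838. The complete suite runs in
about a minute.

## Known limitations

* Two classes only, matching the study design; multi-class SELECT/SIMCA
  are out of scope.
* The SIMCA component counts per class default to 4 (clinical) and 3
  (spectral, after reduction to 10 variables); the published analysis
  states 4 PCs for the clinical models and is silent for the spectra.
  `pipeline_config()` exposes both.
* JCAMP-DX support is a read-only convenience for single AFFN spectra;
  vendor binary formats are not read.
* The rule engine evaluates four of the five NCEP-ATP-III criteria; waist
  circumference is absent from the data model by design.
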