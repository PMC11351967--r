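---
title: "Quantifying fibrous-cap burden from IVOCT pullbacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fibrous-cap burden from IVOCT pullbacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octplaque)
```

## The measurement problem

Intravascular OCT resolves the fibrous cap — the tissue layer separating
the lumen from a lipid core — at a resolution (~10–20 µm) where its
thickness can be measured directly. Thin caps are the classical marker of
plaque vulnerability, but a cap is a surface, not a point: how much of the
lumen wall is covered by cap, and by how thin a cap, is a three-dimensional
quantity that a single cross-section cannot express. `octplaque` computes
that quantity — thickness-stratified fibrous-cap surface area and burden —
from segmented pullbacks, alongside the conventional per-frame lumen,
calcium, and cap metrics, and provides the cohort-level inference chain
that asks which of these features is associated with a binary clinical
outcome.

The package starts from *segmentations*, not raw imagery: each frame is an
integer label mask (background 0, lumen 1, calcium 2, lipid 3, fibrous cap
4) with calibration metadata (in-plane pixel size; frame pitch, derivable
as pullback speed / frame rate, e.g. 36 mm/s at 180 fps → 0.2 mm).
Automatic segmentation is upstream of this package and out of its scope.

## Ray-casting geometry

All angular measurements are made relative to the center of mass of the
lumen. `cast_rays()` walks outward from the centroid along `n_rays`
uniformly spaced directions (default 360, i.e. 1° sampling), sampling the
mask at half-pixel steps, and records per ray:

* the **lumen boundary radius** — the first lumen → non-lumen transition,
  placed sub-pixel at the midpoint between the last inside and first
  outside sample (linear interpolation of the boundary indicator);
* the **calcium extent** — inner and outer radius of the calcium label,
  giving thickness (outer − inner) and depth (inner − lumen radius);
* the **cap thickness** — the total radial extent of fibrous-cap label on
  the ray.

Design choices the data model does not dictate, fixed and documented here:
the angle origin is the image +x axis (only angular *extents* enter the
feature set, so the origin is immaterial); cap thickness is measured
radially along the ray rather than normal to the lumen boundary, which is
the measurement the centroid-ray geometry supports (for the near-circular
lumens of coronary arteries the difference is second-order); a lumen whose
centroid falls outside the lumen label (non-star-shaped) is flagged with a
warning and measured from the centroid regardless.

Per-frame features follow: lumen area from the pixel count; minimum and
mean lumen diameter from diametrically opposed ray pairs
(`r(θ) + r(θ+180°)`); angular extents as (number of rays on which the
tissue is present) × (angular spacing), so disjoint arcs sum; cap
cross-sectional area per thickness class by assigning each cap pixel to
the class of its nearest ray.

Cap thickness classes use the thin-cap convention: class 1 ≤ 65 µm
(inclusive), class 3 ≥ 150 µm (inclusive), class 2 strictly between, T
their union. Values exactly at a boundary go to the outer classes,
following the defining inequalities.

## Lesion aggregation and the en-face surface

Frame features aggregate over the lesion span (the stented segment,
supplied in metadata — there is no automatic lesion detection): min/mean
for lumen metrics; per-frame maxima ("max" fields) and minima ("min"
fields) over the frames where the tissue is present — absent frames are
skipped, not zero-filled, so a single calcium frame defines both extremes.
Lesion length is the frame count × frame pitch.

The 3-D cap features live on the unrolled lumen surface, coordinates
(θ, z):

* **FC surface area** of class *c*:
  `SA_c = Σ_frames (Σ_{rays of class c} r(θ) Δθ) × pitch`;
* **lumen surface area**: the same sum over all rays;
* **FC burden**: `100 × SA_c / lumen surface area`, a percentage in
  [0, 100].

The totals are computed as the literal sum of the three class values
(`SA_T = SA_1 + SA_2 + SA_3`, left-associated), so class conservation is
exact in floating point, not merely within tolerance.

Note that `r Δθ` is the arc length seen from the lumen centroid; for a
non-circular lumen this is the centroid-projected surface, consistent
between numerator and denominator of the burden. With this definition the
burden of a constant-radius lumen covered by a ϑ-degree arc is exactly
ϑ/360 — an identity the test suite exercises.

## The inference cascade

`run_pipeline()` reproduces the standard outcome-study chain on a
lesions × features table with a binary outcome:

1. **Group comparison.** Pooled-variance Student t-test for continuous
   features (Welch available behind a flag), Pearson χ² without continuity
   correction for the binary flags. Missing values drop per feature;
   zero-variance features report `NA` with a warning.
2. **Redundancy pruning.** Pairwise Spearman |ρ|; average-linkage
   clustering on 1 − |ρ| for the heatmap ordering; features pairwise
   linked at |ρ| > 0.9 form connected components, and each component
   retains its most representative member — the one with the highest
   median |ρ| to the rest, ties broken by the fixed feature order. This
   rule deliberately keeps a *total* (e.g. FC surface area-T) over its
   near-duplicate class components: a total is the component-noise-free
   summary of its group, whereas selecting on outcome association within
   a group of ρ ≈ 0.95 near-copies is statistically a coin flip — the
   difference between two such features' test statistics is comparable to
   its own sampling noise. Keeping pruning outcome-free also preserves the
   layering of the cascade: redundancy is a property of the features, not
   of the endpoint.
3. **Univariate logistic regression** per retained feature: maximum
   likelihood, OR = exp(coefficient), Wald 95% CI. Complete or
   quasi-complete separation (diverging slope) is flagged and reported
   with a [0, ∞] interval rather than raised as an error.
4. **Multivariate logistic regression** on the features with univariate
   p < α (default 0.05). A rank-deficient design is an error naming the
   collinear columns; an events-per-variable ratio below 10 warns. No
   penalization or Firth correction is applied — near-separation inflates
   some intervals, and the pipeline reports that honestly rather than
   changing the estimator.
5. **ROC** for each multivariate-significant feature: empirical AUC in
   the Mann–Whitney formulation (ties count half), a stratified percentile
   bootstrap CI (cases and controls resampled separately; 2000 replicates
   by default, seeded), and the optimal cutoff as the observed threshold
   maximizing sensitivity + specificity, ties resolved toward the smaller
   (more sensitive) threshold.

Everything downstream of the seed is deterministic; two runs with the same
configuration serialize to byte-identical JSON reports.

### A note on post-selection behavior under the null

Selecting features at α = 0.05 and refitting the selected set jointly does
not control the family-wise error of the final claim: with ~20 retained
features, a permuted (null) outcome still yields at least one univariate
hit in a substantial fraction of datasets, and when exactly one feature is
selected the "multivariate" model *is* the univariate model, so the hit
survives by construction. The pipeline reproduces this behavior because it
is the behavior of the procedure it implements — it applies no
multiple-testing correction, matching field practice for this analysis
style. Users should treat a lone marginally significant survivor with
corresponding skepticism.

## The synthetic module

Two generators make every stage testable without clinical data.

**Vessel phantoms** (`lesion_spec()`). A lesion is described analytically:
a lumen radius function r(θ, z), cap arcs (start, end, thickness — a
constant or a function of θ, enabling ramps that cross class boundaries),
and calcium arcs (thickness, depth). `truth_features()` evaluates the 31
features by fine angular quadrature of their defining integrals — no
rasterization — while `rasterize()` renders label masks at a chosen pixel
size (≤ 20 µm, the imaging-resolution regime). The pair provides a
round-trip oracle: quantified raster features must agree with the analytic
truth within raster tolerance, and the error must shrink as the pixel size
drops. Tolerances documented from the measured battery: the 90°, 0.1 mm
arc reference phantom at 10 µm pixels recovers surface area within 3%,
angle within 2°, burden within 1 point, and calcium thickness/depth within
2 pixels; small thin arcs at 20 µm pixels are held within 10% (one ray and
one pixel of boundary slop is a larger relative share of a 10–20° arc).
Eccentric-lumen fixtures offset the vessel from the image center so the
centroid ≠ image-center path is exercised.

**Simulated cohorts** (`cohort_spec()`). A standard-normal latent severity
s drives FCSA-T = exp(μ + σs); the defaults μ = 0.6, σ = 1.0 give mean
3.0 mm² with SD 3.9 mm², reproducing the strongly right-skewed,
mean ≫ median distribution of cap surface area in diseased cohorts. The
class split is a patient-level Dirichlet(6, 120, 90) draw — class 2
dominates, the thin-cap class is smallest and most variable — applied to
both surface areas and frame areas, so per-class features are the
near-duplicates (ρ > 0.9) of their totals that the pruning stage exists
for. Nuisance features are tiered the way real cohort tables are: cap
angle, frame cap area, calcium angle/thickness and two vulnerable-plaque
flags correlate with severity at ρ_nuis (default 0.45); lesion length and
the remaining flags at ρ_nuis/2; lumen metrics, minimum-type calcium
metrics and minimum cap thickness are null. Burdens divide by a
lumen-surface proxy with realistic dispersion (lumen-area CV ≈ 0.45,
lesion-length log-SD 0.4, plus within-pullback profile variability), and
the diameters are exact monotone transforms of the areas.

The outcome is Bernoulli with logit(p) = β₀ + β·z, z the standardized
(raw-scale) FCSA-T. β₀ is calibrated by root-finding so the marginal event
rate matches the target (default 0.231, the 24/104 regime of the
motivating study design); an unattainable target is an error. The default
β = 2.4 per SD is calibrated so that FCSA-T discriminates the outcome at
AUC ≈ 0.85 — the discrimination level the generator emulates — and implies
an OR of roughly 1.8 per mm² at the default FCSA scale. Because the true
model is linear in (standardized) raw FCSA-T, the univariate fit on the
raw feature is correctly specified, and correlated proxies carry no
conditional signal in the joint model: with high probability the cascade
ends with FC surface area-T as the lone multivariate-significant feature,
which is the structural ground truth the pipeline tests assert. For
parameter-recovery experiments, set `beta_fcsa = log(2.38)` (a reference
multivariate effect size) and verify Wald-interval coverage on the
standardized feature, as `scripts/acceptance.R` does.

What the generator does **not** emulate: OCT speckle and texture (inputs
are labels, not images), segmentation error, within-lesion longitudinal
correlation of frames beyond the shared severity, competing risks or
censoring (the outcome is a plain binary), and covariate effects such as
age or diabetes. Passing tests therefore validate the measurement
geometry and the statistical machinery, not the clinical segmentations
upstream.

## Numerical choices

* Ray sampling at pixel_size/2; boundary placement at the sample midpoint;
  n_rays must be even so diametric chords pair up exactly.
* Quadrature for analytic truth at 7200 points (0.05°), midpoint rule.
* Problem sizes in the test battery: the reference phantom uses 50 frames
  at 10 µm pixels; the randomized conservation battery 25 phantoms at
  20 µm; recovery experiments 50 replicates of n = 2000; the binormal AUC
  check 10⁵ scores per class. These sizes put Monte-Carlo noise well below
  the asserted tolerances while keeping the suite fast.
* Calibration of β₀ by `uniroot` on the mean model probability
  (tolerance 10⁻¹⁰) on the drawn sample, so the realized event rate
  differs from the target only by binomial noise.
* All seeds flow from a single integer; bootstrap seeds derive from it by
  fixed offsets.

## Limitations

* Cap thickness is radial, not normal-to-boundary; for markedly eccentric
  lumens the radial chord overestimates the normal thickness.
* The en-face surface uses centroid arc length `r Δθ`, not the true
  boundary arc length; for non-circular lumens both SA and lumen surface
  share this convention, so the burden ratio is less affected than either
  term.
* Non-star-shaped lumens are measured at the first boundary crossing and
  flagged; the geometry is not designed for them.
* Wald inference in small cohorts with near-separation is fragile; the
  pipeline warns (events-per-variable, separation flags) but does not
  switch estimators.
* The burden definition is a percentage of lumen surface area and is
  bounded by 100; burden values from other software with different
  normalizations are not comparable.
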