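---
title: "canopydiv: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{canopydiv: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
assumes, which parameters matter, what the synthetic generator does and does
not emulate, and where the design was genuinely open. It states no empirical
result that the test suite does not itself compute.

## 1. The world the generator states

`generate_species_pool()`, `generate_climate_grids()`, `generate_scene()`
and `generate_field_survey()` build a seeded landscape with the statistical
structure the downstream analysis assumes.

**Species pool.** Each species carries a phenology class (evergreen =
1/deciduous = 0, Bernoulli 0.5), wood density (normal 0.60 ± 0.12 g cm⁻³,
clipped to 0.25–1.0 — tropical hardwood range), mean canopy spread (uniform
6–14 m, so crowns span 2–3 pixels at 4 m), a log-normal DBH distribution
truncated to 0.04–1.43 m (the range the field protocol reports), and niche
coefficients for the eight covariates. The rainfall coefficient is
`+|N(0.8, 0.3)|` for evergreen and the negative for deciduous species: the
landscape therefore *encodes* the evergreen-share-increases-with-rainfall
gradient, and the property test regresses per-reserve evergreen crown share
on reserve rainfall and asserts a positive slope. A configurable fraction of
species is reserve-specific; the rest occur in at least two reserves.

**Signatures.** A smooth base vegetation spectrum (green peak, red edge, NIR
plateau, water dips at 1450/1940 nm, SWIR decline) plus two Gaussian bumps
per classification window (550–650, 750–1250, 1500–1750, 2000–2250 nm),
amplitude `N(0, 0.04)`, width 15–45 nm. Offending pairs are redrawn until
all pairwise spectral angles over the classification windows exceed
`min_separation_deg` (default 3°). Separability is thus *tunable and
guaranteed*, which is the point: the classification acceptance floor
(overall accuracy ≥ 0.90) certifies the chain, not the difficulty of real
imagery, where reported accuracies are 20 points lower.

**Climate.** Reserve blocks are laid west→east on a shared 0.005° grid. The
six covariates are fixed as decadal mean rainfall (CC1, spanning
1140.13–2757.60 mm), wet-season rainfall (0.72·CC1), rainfall seasonality,
decadal mean temperature (24.93–28.08 °C, decreasing with rainfall), maximum
monthly temperature (+4.2 °C) and temperature seasonality. Any six with a
rainfall-dominant gradient satisfy the contract; the exact set in the source
study is not published in its main text. Each cell is the reserve mean plus
`N(0, noise_sd_frac × between-reserve range)`; `noise_sd_frac = 0` gives
exactly the reserve means (a tested contract), and the default 0.1 reflects
within-reserve variability at the scale of satellite rainfall products.

**Scenes.** Crowns are placed at uniform random centres; species are sampled
with probability ∝ `exp(niche · z(local covariates))`; discs are rasterized
at 4 m with taller-tree-wins overlap, matching an airborne sensor's
canopy-dominant view. Pixel spectra are `signature × brightness + N(0,
noise_sd)` clipped to [0, 1]; the brightness field is a smooth sinusoid
surface in `brightness_range` (default 0.8–1.2) and the default noise is
0.005 reflectance — post-atmospheric-correction noise levels. The non-forest
background is spectrally flat (NDVI ≈ 0) so NDVI thresholds (0.4 drier /
0.6 wetter reserves) remove it. What the generator does **not** emulate:
atmospheric residuals, BRDF, topographic shading, mixed pixels at crown
edges beyond the winner-takes-pixel rule, phenological spectral change.
A green end-to-end test therefore establishes correctness of the chain, not
expected real-world accuracy.

## 2. Spectral processing

Band selection is purely interval-driven (keep ≥ 411 nm, drop 1348–1428 and
1778–1949 nm; classify on the four windows above); the counts 368 and 224
on the ideal 5 nm grid are emergent, never hard-coded. BNORM scales each
spectrum to unit Euclidean norm — idempotent and scale-invariant, which is
its purpose (removing multiplicative brightness).

**MNF.** Noise covariance comes from horizontal shift differences
`(x[r,c] − x[r,c+1])/√2`; the data covariance is noise-whitened and
eigendecomposed, so pure-noise components have eigenvalues near 1 (verified
by Monte-Carlo) and retention keeps eigenvalues above `snr_threshold`
(default 2, minimum 3 components — the per-scene retained counts of the
source study are unpublished). One design choice was forced by the synthetic
geometry: with 2–3 px crowns, unrestricted shift differences straddle crown
boundaries and the "noise" estimate absorbs between-species contrast,
destroying class separability after whitening. `fit_mnf(..., groups =)`
therefore restricts difference pairs to samples sharing a group (crown id),
the synthetic counterpart of estimating sensor noise over homogeneous
patches. With `groups = NULL` the estimator is exactly the textbook one.

## 3. Classification

Training crowns are those that still own their centre pixel after
rasterization (canopy-visible individuals, as GPS-marked in the field);
spectra are taken from the core 60 % of the crown radius and pixels
overwritten by taller neighbours are dropped — emulating expert-delineated
pure crown polygons. The classifier never sees the truth map at prediction
time. The 75/25 split is per-class and disjoint (a with-replacement split
would leak duplicates across the partition). SMOTE raises every minority
class to the majority count by convex interpolation between same-class
neighbours; the majority class and the label set are never altered. The
random forest is a from-scratch Rcpp implementation (CART, Gini, bootstrap,
OOB votes) because no forest package exists in the target environment;
`(mtry, ntree)` are grid-searched on OOB accuracy and prediction ties break
to the lowest class index for cross-platform determinism.

## 4. Gridding

Plots are 18 × 18 px ≈ 0.52 ha, the smallest integer window ≥ 0.5 ha at
4 m; up to three non-overlapping seeded placements per 0.005° cell, each
requiring ≥ 70 % labelled pixels. Pixel counts become individuals via
`round(n_px · 16 / π(spread/2)²)` with a minimum of 1 when any pixel is
present — the rounding rule is a documented choice (the source is silent),
and homogeneity (doubling pixels doubles abundance ± 1) is tested. Cells
with no qualifying plot are excluded and logged, and "others" participates
like a species with the pooled mean canopy spread.

## 5. The supervised-component GLM

Components maximize `crit(u) = s log φ(u) + (1−s) log ψ(u)` on the unit
sphere, subsequent components constrained `u' X'X u_g = 0`:

* `φ(u) = Σ_j ((Su)_j² / u'Su)^l` with `S = cov(X)` — the variable-powered
  inertia of the component among the standardized covariates. At `l = 1`,
  maximizing φ alone is exactly the first principal component (tested
  against an eigendecomposition oracle).
* `ψ(u) = Σ_s [ℓ_s(components, extras, Xu) − ℓ_s(components, extras)]` — the
  per-species Poisson log-likelihood gain of adding the candidate component.
  Its gradient uses the envelope theorem, `Σ_s γ̂_s X'(y_s − μ̂_s)`, so each
  optimizer iteration costs one IRLS fit per species.

Optimization is a projected, normed gradient ascent with step halving: a
step is only accepted if the criterion does not decrease, so the criterion
trace is non-decreasing by construction (asserted per step in the tests).
Convergence: loading change < 1e-6 or three consecutive negligible gains;
maximum 200 iterations with a warning and best iterate on failure.
Defaults `s = 0.5`, `l = 1`; `K` may be chosen by cross-validated median ρ
(`select_k_scglr()`), and the demo config fixes `K = 3` for runtime. The
Poisson family with log link is a documented choice (abundances are
extrapolated counts; the source names no family). Elevation and soil enter
the per-species GLMs directly rather than the component construction,
mirroring the covariates/additional-covariates split of the
supervised-component literature.

Two exact contracts anchor the implementation: with `K = rank(X)` the
per-species deviances match independent full Poisson GLMs to 1e-6 relative
(the components then span the covariate space), and `component_inertia()`
reports the projection share `‖P_{f_h}X‖²/‖X‖²`, whose cumulative value
reaches 100 % at full rank — the naive `‖Xu_h‖²/total` does not have that
property for non-eigenvector loadings, which is why the projection form was
adopted.

**Spatial validation.** Ward (`ward.D2`) clustering of cell coordinates
into 23 blocks; leave-one-block-out refits; held-out predictions pooled
across folds (each cell used exactly once) before per-species Spearman
correlation. Pooling was chosen over per-fold averaging because it is
deterministic and uses every cell once.

## 6. Community structure

Correspondence analysis is the SVD of
`D_r^{-1/2}(P − rc')D_c^{-1/2}`; total inertia equals χ²/n (tested against a
hand-written χ² oracle to 1e-10) and all-zero rows/columns are dropped with
a warning. Supplementary rows are projected through the column standard
coordinates; the projection of a training row reproduces its fitted score
identically because the right singular vectors are orthogonal to `√c`.
Assemblage types are Ward cuts of the first five axes. The source's
"uncertainty values" are undefined there; the documented stand-in is
bootstrap label instability: resample cells, re-cluster, match types to the
original by greedy maximum overlap, and count how often each cell changes
type. It is 0 in the separated-clusters limit and grows monotonically with
score noise (tested on a three-level noise ladder). "% similarity" between
types is likewise unnamed in the source; Sørensen on type species sets
(species occupying ≥ 5 % of a type's cells) is the documented choice.

## 7. Functional traits and diversity

Per species and reserve, index traits are crown-pixel values trimmed to the
central 95 % (2.5–97.5 percentiles) and averaged — the trimming reading of
"95 % confidence interval values were retained" is deliberate, because it
preserves multiple values for the subsequent averaging step that the
procedure requires. Maximum DBH is the mean of the two largest records;
multi-reserve species get the mean of reserve means; wood density and
phenology are constant across reserves. CWMs are `Σ p_i t_i`; the phenology
CWM is the evergreen abundance share.

FRic is the exact convex-hull volume of the community's trait points
(incremental 3-D hull in Rcpp; degenerate inputs — fewer than four affinely
independent points — return 0 with a flag rather than an error). Traits are
standardized to zero mean and unit variance over the species pool before
hull computation (common practice; the source is silent), so volumes are
comparable across trait sets. FDiv follows the gravity-centre form: `G` is
the centroid of the hull vertices, `d̄` the unweighted mean distance of the
community's species to `G`, and
`FDiv = (Σp_i(d_i−d̄) + d̄)/(Σp_i|d_i−d̄| + d̄)`. Zero-abundance species are
excluded before evaluation (they are not community members), which is what
makes FDiv invariant to padding the community matrix with absent species.
Only the two 3-trait sets (biophysical, biochemical) are computed; the
source never combines them into six dimensions.

## 8. Dark diversity

`b_ij = (1/S_i^(−j)) Σ_{k≠j, x_ik=1} M_jk/N_k`, excluding the target
species from both the sum and the richness — the prevailing Beals-smoothing
convention, which the source delegates to its references. The fast
matrix-product implementation is checked for exact equality (< 1e-12)
against a brute-force double loop on 100 random matrices. Thresholds are
per-species 5 % quantiles (type-7 linear interpolation, documented — the
source is silent on both the quantile method and per-species vs global
scope) of Beals values over occupied plots; plots enter only with richness
strictly greater than five. Membership is monotone non-increasing as the
quantile grows (property-tested). The injection–recovery test deletes a
common species from 20 % of its generator-placed plots and requires ≥ 80 %
of deletions to reappear in dark diversity.

## 9. Pipeline, artifacts, determinism

One JSON config governs a run; every stage draws its seed from the master
seed, and the manifest records per-stage timings, muffled warnings and md5
checksums. Rerunning a config reproduces every artifact checksum (asserted
by the acceptance suite). Artifacts are plain text (CSV, JSON, Newick-like
tree text): the execution environment provides no GeoTIFF/ENVI/GeoJSON/YAML
libraries, so maps are CSV matrices with JSON sidecars and configs are
JSON — schemas, not formats, are the contract. Stages decouple through
these files; disabling classification with a supplied map path leaves the
downstream output byte-identical (tested).

## Known limitations

* The synthetic world is much cleaner than AVIRIS-class imagery: perfect
  registration, i.i.d. Gaussian noise, no mixed pixels or shadows; accuracy
  and ρ_cv figures from the demo are upper bounds on realism.
* The Rcpp random forest is deliberately minimal (no class weights, no
  probability output, no variable importance).
* SCGLR hyperparameters `s`, `l`, `K` and the Poisson family are documented
  defaults, not inferred choices of the source study.
* The hull algorithm is exact only in 3-D; other FD indices (FEve, FDis,
  RaoQ) are out of scope.
* Geographic coordinates are idealized (0.005° ≡ 500 m exactly); no
  projection handling.
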