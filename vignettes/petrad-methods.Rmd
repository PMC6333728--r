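---
title: "petrad: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petrad: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`petrad` implements an FDG-PET radiomics survival pipeline: convert a PET
volume to SUV, delineate the primary tumor with an adaptive SUV threshold,
quantise the VOI at seven gray levels, extract a 665-feature 3D texture
catalogue per gray level, screen and discover prognostic feature vectors
with LASSO-Cox, score the published two-feature signature (FVX), and
evaluate survival stratification. This vignette records the models, the
parameters that matter, and the choices made where the design was
genuinely open.

## Coordinate and unit conventions

Volumes are 3D arrays `dim = c(nx, ny, nz)` with x the fastest axis and z
the slice axis; voxel `(i, j, k)` (1-based) sits at
`origin + (c(i, j, k) - 1) * spacing` in mm. Masks live on the PET grid —
no resampling is ever performed, and voxel sizes are deliberately *not*
standardised across scanners; texture offsets are taken in index space at
distance 1 voxel, with no correction for anisotropy.

SUV is the body-weight convention: `SUV = C / (D(t) / W)` with tissue
concentration `C` (kBq/ml), decay-corrected injected dose
`D(t) = D0 2^(-t/T_half)` (kBq, 18F half-life 109.77 min) and weight `W`
(kg). Lean-mass and body-surface variants are out of scope. SUVpeak uses a
1 ml sphere neighbourhood built in physical units from the voxel spacing
(radius `(3V/4pi)^(1/3)` ≈ 6.2 mm, centre-to-centre distances, restricted
to in-mask voxels so that `peak <= max` holds by construction); the sphere
volume is a parameter (`peak_kernel_ml`).

## Segmentation

Delineation starts from a seed voxel in the lesion hot spot and grows the
26-connected component above `fraction x SUVmax`, where SUVmax is the
global maximum of the seed's component (iterated to a fixed point, since
the component depends on the threshold). Defaults: initial fraction 0.40,
adaptation step 0.05, floor 0.20, inclusion gate 5 ml (inclusive). The
"does the VOI cover the tumor?" visual check of semi-automatic practice is
operationalised as a measurable surrogate: coverage of a supplied
reference extent mask, with the threshold lowered until coverage reaches
0.90 or the floor is hit (then flagged). The step of 0.05 reflects that
discrete thresholds of 40% and 30% dominate in practice; the 0.20 floor
prevents background flooding. Manual edits are set operations that flag
the mask; the single-component property is re-checked and reported, not
enforced.

## Quantisation and texture matrices

Gray levels default to 4, 8, 16, 32, 64, 128, 256. Bins are equal-width
over the in-VOI min–max range:
`label = ceiling(G (v - min) / (max - min))` clamped to `[1, G]`; a
constant VOI maps to label 1. Min–max binning makes the quantised texture
features invariant to global SUV rescaling; a fixed-bounds mode exists for
absolute binning but is not the default.

* **GLCM** — pair counts at offset distance 1 over the 13 unique 3D
  directions, *summed* into one matrix before statistics (merged-matrix
  strategy, not per-direction averaging), then symmetrised.
* **GLRLM** — maximal equal-label runs along the same 13 directions,
  aggregated; every in-mask voxel lies in exactly one run per direction,
  giving the mass identity `sum(R[i,j] j) = 13 n`.
* **GLSZM** — 26-connected equal-label zones; `sum(Z[i,s] s) = n`.
* **NGTDM** — 26-neighbour in-mask neighbourhood means; voxels with no
  in-mask neighbour are excluded from the counted total.

The two signature constituents are defined exactly as: size-zone variance
`SzVarianc = sum p(i,s) (s - mu)^2` with `p` the fraction of zones and
`mu = sum p s` (gray-level independent), and the Amadasun–King complexity
`Complex = sum_{i,j} |i - j| / (n (p_i + p_j)) (p_i s_i + p_j s_j)`.
Degenerate single-level VOIs take their limits (variances 0, complexity
0); statistics without a finite limit (e.g. GLCM correlation under zero
marginal variance) are recorded missing with a reason — never silent NaN.

## The 665-feature catalogue

The exact composition of the original 665-feature catalogue is not
recoverable from its description, so the package defines and documents its
own, which is configurable and totals exactly 665 per gray level:

| block | features |
|---|---|
| first-order (raw SUV; entropy/uniformity on the G-bin histogram) | 19 |
| shape (two surface estimators, sphericity, compactness, diameter) | 10 |
| fractal (box-counting dimension of the boundary) | 1 |
| GLCM | 22 |
| GLRLM | 16 |
| GLSZM | 16 |
| NGTDM | 5 |
| 8 wavelet sub-bands x (13 first-order + 22 + 16 + 16 + 5 texture) | 576 |
| **total** | **665** |

Shape, fractal and the wavelet transform do not depend on G and are
computed once, then repeated in each gray level's set so that every set is
self-contained. Names follow `<Block>_<Feature>_<G>gl`
(e.g. `GLSZM_SzVarianc_64gl`), wavelet blocks prefixed `W<band>_`.

**Surface area.** Two estimators ship side by side: `SurfaceAreaFace`
counts exposed voxel faces (a 1 mm voxel has 6 mm²) and is exact for
box-like objects, but overestimates any smooth convex surface by a factor
3/2; `SurfaceArea` triangulates the 0.5-isosurface of the box-smoothed
mask by marching tetrahedra and converges to the true area (digitized
spheres reach sphericity 1 within a few percent by radius 10 voxels).
Sphericity and compactness use the mesh estimator, falling back to face
counts for structures too thin to carry an isosurface.

**Wavelets.** No decimated transform is used: the one-level *undecimated*
(stationary) separable transform keeps sub-bands on the input grid, so the
VOI mask applies unchanged — the standard choice for radiomics sub-band
textures. Filters are Daubechies-2 scaled by `1/sqrt(2)` per axis;
with periodic boundary handling the transform is orthonormal and sub-band
energies sum exactly to the input energy, which the tests exploit.
Symmetric (half-sample reflection) boundary handling is the extraction
default since tumors are not periodic objects; the boundary mode is a
parameter. Sub-bands are computed on the VOI bounding box; a box shorter
than the 4-tap filter on any axis records all wavelet features missing
with a reason.

**Fractal dimension.** Box counting over boundary voxels with box sides
1, 2, 4, ... capped at a quarter of the largest array dimension, so the
log–log regression reflects small-scale scaling rather than the object's
extent; at least 3 ladder points are required.

## Signature discovery and scoring

* **Volume screening.** Features with `|Spearman rho| >= 0.7` against
  tumor volume are divided by volume; zero-variance features are left
  untouched and logged. The step is idempotent once a normalised feature
  no longer crosses the threshold.
* **LASSO-Cox.** Per gray level, an L1-penalised Cox partial likelihood
  over that level's features; glmnet standardises internally and weights
  are reported on the original feature scale. The penalty comes from
  10-fold cross-validated partial-likelihood deviance; both the minimum
  and 1-SE rules are exposed and the minimum is the default (the original
  analysis does not state its rule; the minimum recovers planted signals
  more reliably at these cohort sizes, while 1-SE is the sparser choice
  used in the null-cohort tests). Fold assignment is the only randomness
  and is seeded. At least 20 events are required.
* **Model selection across gray levels.** The criterion that crowned one
  feature vector "most predictive" is not stated in the source analysis;
  the package uses cross-validated Harrell C-index of the fixed score on
  held-out folds, with ties broken toward fewer terms, then lower gray
  level — a documented surrogate.
* **Scoring.** `score = sum(weight x feature)`, exactly linear. The
  published signature ships as `inst/extdata/fvx_published.json`:
  `+0.128 x GLSZM_SzVarianc_64gl - 0.018 x NGTDM_Complex_64gl`.
* **Dichotomisation.** Median split sends scores equal to the median to
  the low-score group. The ROC-based cutoff maximises Youden's J against
  death-before-median-OS (patients censored before the median OS are not
  evaluable for that label and are excluded from the ROC). The optimal
  log-rank cutoff ("Kmroc"-style maximally selected statistic) searches
  interior candidate splits leaving at least 10% of the cohort per group.

## Survival statistics

Kaplan–Meier estimation and the log-rank test delegate to the survival
package; Cox models use the Efron tie approximation (the source is silent
on ties), two-sided tests and 95% Wald intervals throughout. Separation
and non-convergence are recorded on the result (`flags`), not raised.
Backward stepwise elimination removes the largest Wald p above 0.05, all
candidates entering as continuous variables. ICC comes from the two-way
mean-squares decomposition (ICC(2,1) agreement by default, ICC(3,1)
consistency available). Scanner invariance is summarised by centred,
scaled PCA of the signature constituents and the between/within
mean-square ratio of PC1–PC2 scores across scanner groups (≈1 under
invariance).

## Power calculation

The planning target (N = 203 for HR 1.78, two-sided alpha 0.05, power
0.75, median survival 2.92 y, median follow-up 2.17 y, yearly censoring
0.012) names no formula, so the package calibrated once among standard
events-formula variants, froze the winner, and documents it:

1. events by **Freedman**:
   `D = (z_{1-a/2} + z_{1-b})^2 (1 + HR)^2 / (1 - HR)^2` (= 88.2);
2. exponential survival, reference arm hazard `log(2)/2.92` per year,
   high-risk arm multiplied by HR;
3. follow-up uniform on `[0, 2 x 2.17]` years — uniform accrual with
   analysis at study end, so the *median* follow-up equals the stated
   value — plus independent exponential loss to follow-up at 0.012/y,
   giving per-arm event probabilities in closed form;
4. per-arm rounding: `N_i = ceiling(D/2 / P_i)`, total `N = N_1 + N_2`.

This variant uses every stated planning input, returns exactly 203, and
is strictly decreasing in |log HR| and increasing in power, which the
tests check. (The Schoenfeld `4(z+z)^2/log^2 HR` variant with a
sqrt-HR arm split and administrative follow-up returns 205–207 under the
same inputs and was rejected by the calibration.)

## Synthetic data: what it does and does not emulate

The phantom is a hard-edged sphere (default ~30 ml, SUV 10 on background
1, 4 mm voxels — a medium-large lesion at routine whole-body resolution)
with intra-tumor heterogeneity from a Gaussian random field (8 mm
correlation length, amplitude 2 SUV) and additive Gaussian noise (SD 0.1).
A single smoothness knob was preferred over blob mixtures because it gives
one interpretable heterogeneity axis. The phantom does *not* emulate
scanner physics — no point-spread blurring of the tumor edge, no scatter,
no reconstruction artefacts — so segmentation accuracy on phantoms bounds
only the algorithmic behaviour, not clinical delineation difficulty. Note
that min–max quantisation deliberately removes the overall texture scale,
so the amplitude knob changes quantised texture only relative to the fixed
noise floor (the knob-monotonicity test operates in that regime).

Synthetic cohorts draw AR(1)-correlated feature vectors (two designated
features carrying log-hazard weights ±log 1.8 per SD, echoing the
published signature's sign pattern and the validation-scale effect size),
exponential survival around a 25-month baseline median, exponential loss
to follow-up (0.001/month) with an 85-month administrative cut-off, and
stage/scanner labels drawn from training-cohort-like frequencies. These
defaults are the package's study conditions: cohort-level hazard ratios
or p-values from any specific patient population are not reproduction
targets.

## Problem sizes and numerical notes

The shipped tests run the full catalogue on the default ~30 ml phantom
(seven gray levels, about 10 s), oracle-verify all four matrix builders
against brute-force enumeration on one hundred random 6³ VOIs, measure
LASSO recovery over 50 replicate cohorts of n = 300 x 50 features, and
estimate Cox bias from 100 replicates at n = 2000 — sizes chosen so the
whole suite completes in about a minute while keeping each estimate's
Monte-Carlo error well inside the asserted margins. All generators are
seed-deterministic; re-running any extraction on identical input is
bit-identical. Known limitations: no DICOM reading (convert series to
NIfTI first), no IBSI-conformance claims, no 2D feature variants, no
competing risks or time-varying covariates.
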