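---
title: "Methods: longitudinal structural covariance networks of gray-matter change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal structural covariance networks of gray-matter change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecov)
```

## The analysis model

`strokecov` analyses longitudinal change in gray-matter volume (GMV) after
sensorimotor stroke in two coupled strands.

**Behaviour.** Each patient's longitudinal test scores are z-transformed
against a healthy control population and summarised by a fitted recovery
curve (response-feature analysis). Two families are compared per patient:
a linear trajectory z(t) = a + b·t and an exponential trajectory
z(t) = z∞ − (z∞ − z0)·exp(−t/τ), with t in days post-stroke and z in
control-referenced standard deviations. The exponential is parametrised
directly by its asymptote z∞ so that the classification rule — linear →
*fast*; exponential with z∞ ≥ −2.5 → *slow*; z∞ < −2.5 → *impaired* — can
be applied to a fitted parameter rather than to an extrapolation. Model
choice uses AIC = 2k + n·ln(RSS/n) with k = 2 (linear) or 3 (exponential);
ties go to the smaller model. A column-centred PCA of the completed
patients × visits z-matrix condenses each patient's recovery into the
first-component expression coefficient; components are retained by the
Kaiser–Guttmann rule (eigenvalue above the mean eigenvalue).

**Structure.** Voxelwise volume-change maps (Jacobian-determinant maps of
the deformation between the two anatomical time points, modulated by the
tissue segmentation and smoothed) are stacked into a scans × voxels matrix
over a brain mask. The matrix is two-way centred — subtract row means and
column means, add back the grand mean — so its row, column and grand means
vanish, and decomposed by SVD. Each component comprises an eigenimage
(unit-norm voxel pattern), unit-norm subject expression coefficients and a
singular value; squared singular values over their total are variance
fractions. Because two-way centering removes one degree of freedom, at most
n − 1 informative components exist for n scans; numerically null trailing
components are dropped rather than reported as zero-variance rows.
Components whose expression crosses a Bonferroni-corrected critical
correlation with external variables (behavioural recovery expression,
lesion volume) constitute the reported covariance networks. Their
eigenimages are thresholded at the 1st/99th percentile of voxel values with
a 32-voxel extent threshold, and the resulting clusters are intersected
with subgroup lesion-density maps.

Assumptions worth stating: the behavioural z-transform treats the control
population as fixed and known; trajectories are assumed monotone-in-mean
within each family (no relapse modelling); the covariance analysis treats
scans as exchangeable rows (no within-subject repeated-measures structure,
since each subject contributes one change map); and Pearson screens assume
an approximately linear association on the unit-norm coefficients (which
makes them scale-invariant in any case).

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| grid | 32×32×32 | voxels | synthetic normalized space; large enough for smooth multi-cluster patterns, small enough for fast simulation |
| voxel size | 2 | mm | reconstructed from the cluster-table consistency of reported voxel counts and cc volumes (8 mm³/voxel) |
| smoothing FWHM | 12 | mm | the conventional kernel for volume-change maps; interpreted as full width at half maximum |
| percentile pair | 1, 99 | % | height thresholds over in-mask eigenimage values |
| extent threshold | 32 | voxels | minimal resolution element of the smoothed maps |
| connectivity | 18 | – | face+edge neighbourhood, a common neuroimaging default; 6/26 configurable and logged per run |
| lesion-density threshold | 0.20 | fraction | strict (>) rule |
| alpha, m | 0.05, 8 | – | family-wise level and comparison count of the correlation screen |
| visit schedule | 0…270 by 30 | days | baseline plus monthly visits to month 9 (10 visits) |
| subgroup sizes | 8/12/8 | patients | fast/slow/impaired cohort composition |
| trajectory noise | 0.5 | z units | visit-to-visit variability of the behavioural series |
| map noise | 0.1 | pattern SD | voxel noise relative to unit per-voxel pattern amplitude |

The packaged 28-patient clinical table carries an internal inconsistency in
its source: the running text describes subgroups of 8/10/8 patients while
the subgroup table prints 8/12/8 (totalling the 28 imaged patients). The
fixture keeps all 28 patients and the generator default follows the 8/12/8
split; the discrepancy is surfaced here rather than resolved. Similarly,
two printed descriptive-row medians (hand-dynamometry month 3, PSO
baseline) differ slightly from the medians of the printed per-patient
columns; the fixture stores the per-patient values verbatim and the package
recomputes descriptives from them.

## What the synthetic generator emulates — and what it does not

The cohort generator draws per-class trajectory parameters (fast: linear
with near-normal baseline and small positive slope; slow: exponential
rising from z0 ∈ [−8, −3] to z∞ ∈ [−2, 0.5]; impaired: exponential
converging to z∞ ∈ [−6, −3]), keeps asymptotes at least 0.5 z-units away
from the −2.5 boundary so that truth labels are well defined, inverts the
z-transform with the generated control statistics to produce raw scores,
and deletes a configurable fraction of cells (default 10/280, the planned
visit miss rate the design emulates). Control population defaults (PSO
6.0 ± 1.0 s, hand dynamometry 36 ± 12 kg, tactile object recognition
28.5 ± 2.5 of 30) were fixed once so that typical raw scores map onto the
conventional z ranges for these tests (e.g. a PSO time of 11 s ↦ z = −5).

The volume generator embeds smooth, mask-orthogonal, unit-amplitude
spatial patterns; each subject map is a loading-weighted sum of patterns
plus voxel noise. Loadings of the first pattern can be tied to a
behavioural vector and to lesion volumes at configured correlation
strengths (jointly, with the residual variance made up by independent
noise). Lesions are spheres with class-specific radii reproducing the
subgroup ordering of lesion volumes (impaired ≫ fast > slow).

Passing tests on these data demonstrate that the machinery — centering,
decomposition, selection, thresholding, volumetrics, statistics — is
correct and that embedded signal of realistic strength is recovered. They
do not show that real post-stroke GMV change contains such signal: real
maps have spatially structured, non-stationary noise, registration
artefacts, lesion-induced intensity distortions and non-spherical lesions,
none of which the generator models. Secondary behavioural scores (grip
force, tactile recognition, ordinal severity scales) are generated only as
class-correlated summaries, not from item-level models.

## Numerical choices

- **Exponential fitting** profiles the time constant: for fixed τ the
  model is linear in (z∞, amplitude), so RSS(τ) is minimised on a grid
  (5, 15, 30, 60, 120, 240 days) and refined by 1-D optimisation around
  the best grid point. This is robust at n = 10 visits where generic
  gradient-based nonlinear least squares frequently diverges, and it makes
  the fallback rule (fit failure → linear, with a warning) essentially
  unreachable. An RSS floor of 1e−24 keeps AIC finite on exact fits, where
  the tie rule then correctly prefers the linear family.
- **AIC, not AICc**, is the default (k = 2 vs 3); the small-sample
  corrected criterion is available via `aicc = TRUE`.
- **SVD path**: for matrices much wider than tall (voxels ≫ scans) the
  decomposition eigendecomposes the n × n scan-covariance matrix; null
  components are detected at eigenvalue scale, since a singular-value
  threshold would inflate rounding noise by the square root.
- **Sign convention**: each eigenimage's largest-magnitude voxel is made
  positive, flipping the coefficient column jointly; configurable
  (`signConvention = "none"`), since the decomposition itself fixes no
  sign.
- **No log transform** of the change maps before centering: the maps enter
  the PCA as Jacobian-scale change values directly; the classic
  scaled-subprofile-model log step is intentionally omitted.
- **Percentiles** use linear interpolation between order statistics
  (type 7), with inclusive tails so the percentile-valued voxel itself
  survives; **lesion density** uses a strict > threshold.
- **Gradients** use central differences with one-sided differences at grid
  borders; **smoothing** uses separable convolution with half-sample
  reflective padding, which preserves the volume total exactly.
- **Degenerate inputs**: constant eigenimages yield empty tails with a
  warning; constant externals yield undefined correlations flagged
  non-selected; all-tied subgroup variables return a degenerate report
  (p = 1) instead of erroring; non-positive Jacobians are counted in a
  warning, not raised as errors.

## Open design decisions

The critical correlation reported by `criticalR()` follows the standard
two-tailed t inversion, r = t/√(t² + n − 2); at n = 28 and α = 0.05/8 this
gives ≈ 0.50. Published tables in this literature sometimes print other
values for nominally the same configuration (tail conventions and the
effective n are often unrecoverable); the implementation reports its own
value and documents the formula. Robust regression defaults to ordinary
least squares — which reproduces the conventional t/F/R² reporting — with
Huber IRLS (tuning constant 1.345) behind `robust = TRUE`. The `fast`
class is triggered by linear-family selection alone; a stricter variant
additionally requiring a normal fitted baseline is available via
`classifyRecovery(strictFast = TRUE)`.

## Problem sizes used in validation

The test suite validates decomposition properties on random matrices up to
10 × 200 against a dense eigendecomposition oracle, labeling against a
brute-force flood fill on 8³ grids, smoothing against dense convolution on
an 11³ grid, pattern recovery on 100 simulated 28-subject datasets at the
default 32³ grid, classification accuracy on 200 simulated cohorts, and
regression recovery on 500 replicates at n = 28. These sizes were chosen to
exercise every code path at full fidelity while keeping the default suite
fast to run.

## Limitations

The package implements the group-level analysis only: it does not register
or segment real images, trace lesions, normalise to a stereotaxic template
or assign anatomical labels to clusters. Lesion masks and volume-change
maps are expected in a common normalized space with identical geometry.
Column-mean imputation assumes missingness unrelated to severity; no
mixed-effects or dropout modelling is provided. Component stability
(bootstrap) and voxelwise permutation significance are out of scope.
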