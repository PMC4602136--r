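# strokecov

Longitudinal structural covariance networks of gray-matter volume (GMV)
change after sensorimotor stroke.

After a cortical stroke, gray matter keeps reorganising for months. When
high-resolution T1 scans are acquired at two time points, tensor-based
morphometry (TBM) turns the deformation that warps one scan onto the other
into a voxelwise volume-change map via the Jacobian determinant of the
mapping. Across a cohort, voxels whose volume changes co-vary form
*longitudinal structural covariance networks*, and a patient's expression of
such a network can be related to how well hand function recovered.
`strokecov` implements that full analysis chain for researchers in stroke
recovery and structural neuroimaging, together with a synthetic-data
generator so that every stage can be exercised and validated without
patient data (which for studies of this kind is rarely shareable).

## The method

**Response-feature analysis (RFA).** Each patient's longitudinal test
scores (the timed picking-small-objects task, PSO, is the primary outcome)
are z-transformed against a healthy control group, missing visits are
imputed by visit means, and two trajectory models are fitted per patient:

- linear: z(t) = a + b·t
- exponential: z(t) = z∞ − (z∞ − z0)·exp(−t/τ)

The winner by Akaike's information criterion, AIC = 2k + n·ln(RSS/n),
classifies the patient: linear → *fast* recovery; exponential converging to
z∞ ≥ −2.5 → *slow*; z∞ < −2.5 → *impaired*. A column-centred PCA of the
z-score matrix (Kaiser–Guttmann selection) yields one expression
coefficient per patient summarising recovery relative to the cohort.

**Scaled-subprofile-model PCA of the TBM maps.** The smoothed volume-change
maps are stacked into a scans × voxels matrix X restricted to a brain mask.
Two-way centering forms the residual matrix

R_ij = X_ij − mean(col j) − mean(row i) + grand mean,

whose row, column and grand means all vanish. The SVD R = U·S·Vᵀ then
yields, per component, an **eigenimage** (voxel pattern, a row of Vᵀ),
**subject expression coefficients** (a column of U) and a singular value
whose square, over the total, is the component's variance fraction.
Components whose expression correlates with clinical variables beyond a
Bonferroni-corrected critical correlation are the reported networks.

**Clusters and lesion overlap.** Network nodes are delineated by height
thresholds at the 1st/99th percentile of eigenimage values plus a 32-voxel
extent threshold, and intersected with subgroup lesion-density maps
(voxels lesioned in >20% of a subgroup). The association stage provides
Bonferroni-gated Pearson screens, Shapiro–Wilk-gated Kruskal–Wallis and
Mann–Whitney subgroup tests, and the multiple regression of behavioural
recovery on network expression, lesion volume and their interaction.

## Worked example

```r
library(strokecov)
m <- runPipeline(defaultRunConfig(seed = 1))
scr <- m$results$screen
scr[scr$selected, c("component", "variance_pct", "variable", "r", "critical_r")]
#>   component variance_pct  variable     r critical_r
#> 1         1         82.4   pc1_pso 0.916      0.504
#> 2         1         82.4 lesion_cc 0.650      0.504
```

The synthetic cohort embeds one behaviour-linked covariance pattern; the
screen recovers it as component 1 (82.4% of variance, r = 0.92 with the
behavioural recovery score, r = 0.65 with lesion volume, both beyond the
critical r of 0.50 at α = 0.05/8). Its clusters and the regression:

```r
m$results$clusters$table[, c("tail", "cluster", "size_vox", "volume_cc")]
#>   tail cluster size_vox volume_cc
#> 1  low       1       48     0.384
#> 2  low       2       39     0.312
#> 3 high       1      101     0.808
m$results$regression
#> Interaction regression (OLS): R2 = 0.868, F(3, 24) = 52.77, p = 1.02e-10
```

Three supra-threshold clusters survive the percentile + 32-voxel extent
thresholds (volumes in cc at 2-mm voxels), and behavioural recovery is
strongly explained by network expression and lesion volume (n = 28,
F on 3 and 24 degrees of freedom). `classifyCohort()` on the same cohort
recovers 25/28 true subgroup labels at the default trajectory noise of
0.5 z-units.

All outputs (cohort tables, fit reports, eigenimages and cluster label
volumes as NIfTI, selection/cluster/overlap tables as CSV, and a JSON
manifest with file checksums) are written to the run directory. A thin
command-line wrapper ships in `exec/`:

```sh
Rscript exec/strokecov run --seed 1 --out runs/demo
```

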