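Package: strokecov
Title: Longitudinal Structural Covariance Networks of Gray-Matter Change
    After Sensorimotor Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing longitudinal structural covariance networks
    of gray-matter volume change after sensorimotor stroke. Implements
    response-feature analysis of behavioural recovery trajectories
    (z-transformation against healthy controls, linear and exponential curve
    fitting with AIC model selection, subgroup classification), tensor-based
    morphometry primitives (Jacobian determinants of deformation fields,
    modulation, Gaussian smoothing, region-of-interest extraction), the
    scaled-subprofile-model voxelwise PCA (double-centred scan-by-voxel
    matrices decomposed by SVD into eigenimages, expression coefficients and
    variance fractions), percentile/extent cluster delineation with lesion
    density overlap volumetrics, and the association stage (Bonferroni-gated
    Pearson correlations, non-parametric subgroup tests, interaction
    regression). A synthetic-data generator produces cohorts and volume sets
    with known ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    igraph,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
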