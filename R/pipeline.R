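# End-to-end run: simulate -> response-feature analysis -> SSM-PCA ->
# clusters -> lesion overlap -> association statistics, with a flat output
# directory and a JSON manifest of config, versions and file checksums.

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their default study
#' conditions: a 32x32x32 grid of 2-mm isotropic voxels, 12-mm FWHM
#' smoothing, 1st/99th percentile height thresholds with a 32-voxel extent
#' threshold at 18-connectivity, a strict 20 percent lesion-density
#' threshold, alpha 0.05 Bonferroni-corrected for 8 comparisons, a
#' baseline-plus-monthly 10-visit schedule and 8/12/8 subgroup sizes.
#'
#' @param seed integer seed driving every random stage.
#' @return named list (serialisable to JSON and back without loss).
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    grid = c(32L, 32L, 32L),
    voxelMm = 2,
    fwhmMm = 12,
    percentiles = c(1, 99),
    extent = 32L,
    connectivity = 18L,
    densityThreshold = 0.20,
    alpha = 0.05,
    m = 8L,
    schedule = defaultVisitSchedule(),
    nPerClass = c(fast = 8L, slow = 12L, impaired = 8L),
    noiseSd = 0.5,
    tbmNoiseSd = 0.1,
    nPatterns = 2L,
    behaviorCor = 0.8,
    lesionCor = 0.3,
    nEigenimagesWritten = 3L
  )
}

# class-specific synthetic lesions: spherical masks whose radii reproduce
# the subgroup ordering of lesion volumes (impaired >> fast > slow)
#' Generate synthetic lesion masks per patient
#'
#' @param classes per-patient recovery class labels.
#' @param mask analysis-grid \linkS4class{VolumeMap} (geometry source).
#' @param seed integer seed.
#' @return list of binary \linkS4class{VolumeMap}s, one per patient.
#' @export
generateLesionMasks <- function(classes, mask, seed = 1L) {
  dims <- dim(mask@data)
  vs <- mask@voxelSize
  base <- c(fast = 12, slow = 9.5, impaired = 22)       # median radius mm
  locus <- list(fast = c(0.70, 0.40, 0.60), slow = c(0.62, 0.58, 0.62),
                impaired = c(0.60, 0.50, 0.55))
  withSeed(deriveSeed(seed, 21), {
    lapply(seq_along(classes), function(i) {
      cl <- classes[i]
      r <- base[[cl]] * exp(rnorm(1, 0, 0.25))
      ctr <- locus[[cl]] * dims + rnorm(3, 0, 1.5)
      makeSphereMask(dims, vs, ctr, r)
    })
  })
}

.writeCsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate, response-feature analysis, SSM-PCA, cluster,
#' lesion-overlap and statistics stages for one configuration, writing all
#' tables, volumes and a JSON manifest into \code{outDir}. Re-running with
#' an identical configuration reproduces identical outputs (checksums in
#' the manifest are bit-stable).
#'
#' @param config list from \code{\link{defaultRunConfig}}.
#' @param outDir output directory (created if needed).
#' @param writeVolumes write NIfTI volumes (eigenimages, labels, density
#'   maps); disable for fast smoke runs.
#' @return the manifest list, invisibly; its \code{results} element carries
#'   the in-memory stage outputs.
#' @export
runPipeline <- function(config = defaultRunConfig(),
                        outDir = tempfile("strokecov_run"),
                        writeVolumes = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  manifest <- list(config = config,
                   package_version = as.character(packageVersion("strokecov")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   choices = list(connectivity = config$connectivity,
                                  percentile_rule = "type 7 (linear interpolation), inclusive tails",
                                  aic_variant = "AIC, k = 2 (linear) / 3 (exponential)",
                                  sign_convention = "peak voxel positive"))
  files <- character(0)
  res <- list()
  tryCatch({
    ## simulate ---------------------------------------------------------
    cohort <- generateCohort(nPerClass = config$nPerClass,
                             schedule = config$schedule,
                             noiseSd = config$noiseSd,
                             seed = config$seed)
    files <- c(files,
               .writeCsv(cohort$scores, outDir, "cohort_scores.csv"),
               .writeCsv(cohort$demographics, outDir,
                         "cohort_demographics.csv"),
               .writeCsv(cohort$truth, outDir, "cohort_truth.csv"))
    res$cohort <- cohort

    ## rfa --------------------------------------------------------------
    stage <- "rfa"
    fits <- classifyCohort(cohort)
    zm <- imputeMissing(cohortZMatrix(cohort, "pso"))
    bp <- behavioralPca(zm)
    pc1 <- bp$coefficients[, 1]
    files <- c(files, .writeCsv(fits, outDir, "rfa_fits.csv"),
               .writeCsv(data.frame(id = rownames(zm), pc1_pso = pc1),
                         outDir, "behavioral_pca.csv"))
    res$fits <- fits; res$behavioralPca <- bp

    ## lesions and tbm maps ---------------------------------------------
    stage <- "ssm"
    mask <- makeEllipsoidMask(config$grid, config$voxelMm)
    lesions <- generateLesionMasks(cohort$truth$class, mask,
                                   seed = config$seed)
    lesCc <- vapply(lesions, lesionVolume, numeric(1))
    files <- c(files, .writeCsv(
      data.frame(id = cohort$truth$id, class = cohort$truth$class,
                 lesion_cc = lesCc), outDir, "lesion_volumes.csv"))
    tbm <- synthTbmDataset(length(pc1), mask, nPatterns = config$nPatterns,
                           behavior = pc1, behaviorCor = config$behaviorCor,
                           lesion = lesCc, lesionCor = config$lesionCor,
                           noiseSd = config$tbmNoiseSd, seed = config$seed)
    x <- buildDataMatrix(tbm$maps, mask)
    decomp <- ssmDecompose(doubleCenter(x))
    files <- c(files,
               .writeCsv(data.frame(id = cohort$truth$id,
                                    decomp@coefficients[, seq_len(
                                      min(5, nComponents(decomp)))]),
                         outDir, "ssm_coefficients.csv"),
               .writeCsv(data.frame(component = seq_len(nComponents(decomp)),
                                    singular_value = singularValues(decomp),
                                    variance_fraction =
                                      varianceFractions(decomp)),
                         outDir, "ssm_variance.csv"))
    if (writeVolumes) {
      for (k in seq_len(min(config$nEigenimagesWritten,
                            nComponents(decomp)))) {
        p <- file.path(outDir, sprintf("eigenimage_%02d.nii.gz", k))
        writeVolume(eigenimageVolume(decomp, k), p)
        files <- c(files, p)
      }
    }
    res$decomp <- decomp; res$tbm <- tbm; res$mask <- mask
    res$lesions <- lesions; res$lesionCc <- lesCc

    ## network selection -------------------------------------------------
    externals <- data.frame(pc1_pso = pc1, lesion_cc = lesCc)
    screen <- selectNetworks(decomp, externals, alpha = config$alpha,
                             m = config$m)
    report <- networkReport(screen)
    files <- c(files, .writeCsv(screen, outDir, "network_screen.csv"))
    res$screen <- screen; res$report <- report
    selRows <- screen[screen$selected & screen$variable == "pc1_pso", ]
    focus <- if (nrow(selRows) > 0) {
      selRows$component[which.max(abs(selRows$r))]
    } else 1L
    res$focusComponent <- focus

    ## clusters -----------------------------------------------------------
    stage <- "clusters"
    cl <- clusterEigenimage(eigenimageVolume(decomp, focus), mask,
                            lowPct = config$percentiles[1],
                            highPct = config$percentiles[2],
                            connectivity = config$connectivity,
                            kMin = config$extent)
    files <- c(files, .writeCsv(cl$table, outDir, "clusters.csv"))
    if (writeVolumes) {
      for (tl in names(cl$labels)) {
        p <- file.path(outDir, sprintf("cluster_labels_%s.nii.gz", tl))
        writeVolume(cl$labels[[tl]], p, datatype = "int16")
        files <- c(files, p)
      }
    }
    res$clusters <- cl

    ## lesion overlap -----------------------------------------------------
    stage <- "overlap"
    dens <- lapply(split(seq_along(lesions), cohort$truth$class),
                   function(i) lesionDensity(lesions[i],
                                             config$densityThreshold))
    overlap <- overlapVolumetrics(cl, dens)
    files <- c(files, .writeCsv(overlap, outDir, "overlap.csv"))
    if (writeVolumes) {
      for (sg in names(dens)) {
        p <- file.path(outDir, sprintf("lesion_density_%s.nii.gz", sg))
        writeVolume(dens[[sg]]$thresholded, p)
        files <- c(files, p)
      }
    }
    res$densities <- dens; res$overlap <- overlap

    ## statistics ---------------------------------------------------------
    stage <- "stats"
    expr <- componentExpression(decomp, focus)
    corr <- correlateWithExternals(expr, externals, alpha = config$alpha,
                                   m = config$m)
    sgt <- subgroupTests(unname(expr), cohort$truth$class,
                         alpha = config$alpha)
    reg <- interactionRegression(pc1, unname(expr), lesCc)
    files <- c(files,
               .writeCsv(corr, outDir, "correlations.csv"),
               .writeCsv(data.frame(
                 shapiro_p = sgt$shapiro_p, kruskal_p = sgt$kruskal_p,
                 mannwhitney_p = sgt$mannwhitney_p), outDir,
                 "subgroup_tests.csv"),
               .writeCsv(reg$coefficients, outDir, "regression.csv"))
    res$correlations <- corr; res$subgroupTests <- sgt; res$regression <- reg
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest$files <- as.list(setNames(unname(tools::md5sum(files)),
                                     basename(files)))
  manifest$results <- NULL
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$results <- res
  manifest$outDir <- outDir
  invisible(manifest)
}
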