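#' @import methods
#' @importFrom stats median quantile sd cor lm coef qt pt pf rnorm runif
#'   shapiro.test kruskal.test wilcox.test optimize setNames complete.cases
#'   .lm.fit vcov residuals
#' @importFrom utils read.csv write.csv packageVersion
NULL

#' VolumeMap: a 3-D scalar image volume
#'
#' Container for a voxel grid with isotropic voxel size and an origin offset,
#' used throughout the package for volume-change maps, tissue segmentations,
#' masks, lesions and eigenimages.
#'
#' @slot data 3-D numeric array of voxel values.
#' @slot voxelSize isotropic voxel edge length in millimetres.
#' @slot origin length-3 numeric offset of the first voxel centre in mm.
#' @slot name optional descriptive label.
#'
#' @examples
#' v <- VolumeMap(array(1, c(4, 4, 4)), voxelSize = 2)
#' voxelVolume(v)  # 0.008 cc per 2-mm voxel
#' @export
setClass("VolumeMap",
  representation(
    data = "array",
    voxelSize = "numeric",
    origin = "numeric",
    name = "character"
  ),
  prototype(voxelSize = 2, origin = c(0, 0, 0), name = "")
)

setValidity("VolumeMap", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be a 3-D array")
  if (any(d < 1L)) return("all three dimensions must be >= 1")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0) {
    return("voxelSize must be a single positive number (mm)")
  }
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' Construct a VolumeMap
#'
#' @param data 3-D numeric array.
#' @param voxelSize isotropic voxel size in mm.
#' @param origin length-3 origin offset in mm.
#' @param name optional label.
#' @return A \linkS4class{VolumeMap}.
#' @export
VolumeMap <- function(data, voxelSize = 2, origin = c(0, 0, 0), name = "") {
  new("VolumeMap", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin), name = as.character(name)[1])
}

#' DeformationField: voxelwise 3-vector displacements
#'
#' A grid of displacement vectors u(x) in mm, stored as a 4-D array with the
#' fourth dimension of extent 3. The mapping it encodes is x + u(x).
#'
#' @slot data 4-D numeric array (nx, ny, nz, 3) of mm displacements.
#' @slot voxelSize isotropic voxel size in mm.
#' @slot origin length-3 origin offset in mm.
#' @export
setClass("DeformationField",
  representation(data = "array", voxelSize = "numeric", origin = "numeric"),
  prototype(voxelSize = 2, origin = c(0, 0, 0))
)

setValidity("DeformationField", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L || d[4] != 3L) {
    return("data must be a 4-D array with 3 displacement components")
  }
  if (!all(is.finite(object@data))) return("displacements must be finite")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  TRUE
})

#' Construct a DeformationField
#' @param data 4-D array (nx, ny, nz, 3) of mm displacements.
#' @param voxelSize isotropic voxel size in mm.
#' @param origin length-3 origin offset in mm.
#' @return A \linkS4class{DeformationField}.
#' @export
DeformationField <- function(data, voxelSize = 2, origin = c(0, 0, 0)) {
  new("DeformationField", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' ControlStats: healthy-control population parameters per test
#'
#' Per-test means and standard deviations of the healthy control group used
#' for the z-transformation of patient scores, plus a sampled control table.
#'
#' @slot mean named numeric vector of per-test control means (test units).
#' @slot sd named numeric vector of per-test control SDs (test units).
#' @slot nControls number of control subjects.
#' @slot controls data.frame of sampled control scores (one row per subject).
#' @export
setClass("ControlStats",
  representation(mean = "numeric", sd = "numeric", nControls = "integer",
                 controls = "data.frame")
)

setValidity("ControlStats", function(object) {
  if (length(object@mean) != length(object@sd) ||
      !identical(names(object@mean), names(object@sd))) {
    return("mean and sd must be named alike")
  }
  if (any(!is.finite(object@sd)) || any(object@sd <= 0)) {
    return("every control sd must be positive")
  }
  if (object@nControls < 2L) return("nControls must be >= 2")
  TRUE
})

#' SSMDecomposition: SVD of a double-centred scan-by-voxel matrix
#'
#' Holds the eigenimages (voxel patterns), subject expression coefficients,
#' singular values and variance fractions of the scaled-subprofile-model PCA,
#' together with the mask bookkeeping needed to back-project eigenimages
#' into volume space.
#'
#' @slot eigenimages components x voxels matrix; rows are unit-norm voxel
#'   patterns.
#' @slot coefficients scans x components matrix of subject expression
#'   coefficients; columns are unit-norm.
#' @slot singularValues non-negative singular values in descending order.
#' @slot varianceFractions fraction of variance per component
#'   (singular value squared over their total).
#' @slot voxelIndices linear indices of in-mask voxels in raster order.
#' @slot maskDim dim of the mask volume the indices refer to.
#' @slot voxelSize voxel size (mm) carried over from the input maps.
#' @slot scanIds per-scan identifiers.
#' @export
setClass("SSMDecomposition",
  representation(
    eigenimages = "matrix",
    coefficients = "matrix",
    singularValues = "numeric",
    varianceFractions = "numeric",
    voxelIndices = "integer",
    maskDim = "integer",
    voxelSize = "numeric",
    scanIds = "character"
  )
)

setValidity("SSMDecomposition", function(object) {
  k <- length(object@singularValues)
  if (nrow(object@eigenimages) != k || ncol(object@coefficients) != k ||
      length(object@varianceFractions) != k) {
    return("component counts disagree across slots")
  }
  if (is.unsorted(rev(object@singularValues))) {
    return("singular values must be in descending order")
  }
  if (any(object@singularValues < 0)) return("singular values must be >= 0")
  if (k > 0 && abs(sum(object@varianceFractions) - 1) > 1e-8) {
    return("variance fractions must sum to 1")
  }
  TRUE
})

# ---- accessors ----

#' @describeIn VolumeMap voxel values as a 3-D array
#' @param x a VolumeMap
#' @export
voxelData <- function(x) x@data

#' @describeIn VolumeMap isotropic voxel size in mm
#' @export
voxelSize <- function(x) x@voxelSize

#' @describeIn VolumeMap volume of one voxel in cc
#' @export
voxelVolume <- function(x) (x@voxelSize / 10)^3

#' Number of components in a decomposition
#' @param x an SSMDecomposition
#' @export
nComponents <- function(x) length(x@singularValues)

#' Singular values of a decomposition
#' @param x an SSMDecomposition
#' @export
singularValues <- function(x) x@singularValues

#' Variance fractions of a decomposition
#' @param x an SSMDecomposition
#' @export
varianceFractions <- function(x) x@varianceFractions

setMethod("show", "VolumeMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeMap%s: %d x %d x %d voxels, %.3g mm isotropic\n",
              if (nzchar(object@name)) paste0(" '", object@name, "'") else "",
              d[1], d[2], d[3], object@voxelSize))
  cat(sprintf("  value range: [%.4g, %.4g]\n",
              suppressWarnings(min(object@data, na.rm = TRUE)),
              suppressWarnings(max(object@data, na.rm = TRUE))))
  invisible(object)
})

setMethod("show", "ControlStats", function(object) {
  cat(sprintf("ControlStats: %d controls, %d tests (%s)\n",
              object@nControls, length(object@mean),
              paste(names(object@mean), collapse = ", ")))
  invisible(object)
})

setMethod("show", "SSMDecomposition", function(object) {
  k <- nComponents(object)
  cat(sprintf("SSMDecomposition: %d scans x %d voxels, %d components\n",
              nrow(object@coefficients), length(object@voxelIndices), k))
  if (k > 0) {
    vf <- round(100 * object@varianceFractions[seq_len(min(k, 5L))], 1)
    cat("  leading variance fractions (%):", paste(vf, collapse = ", "), "\n")
  }
  invisible(object)
})

# internal geometry check shared by voxelwise operations
stopIfGeometryMismatch <- function(a, b, what = "volumes") {
  if (!identical(dim(a@data)[1:3], dim(b@data)[1:3]) ||
      !isTRUE(all.equal(a@voxelSize, b@voxelSize))) {
    stop("geometry mismatch: ", what,
         " must share grid dimensions and voxel size", call. = FALSE)
  }
  invisible(TRUE)
}
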