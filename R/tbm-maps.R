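# Tensor-based morphometry primitives: Jacobian determinants of deformation
# fields, modulation by a tissue segmentation, Gaussian smoothing, ROI
# extraction, and synthetic volume sets with embedded covariance patterns.

# finite-difference gradient of a 3-D array along one axis, central in the
# interior and one-sided at the borders; spacing h in mm
.gradAxis <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  if (n < 2L) stop("grid must have >= 2 voxels along each axis")
  idx <- function(i) {
    args <- list(a)
    args[1 + seq_len(3)] <- lapply(d, seq_len)
    args[[1 + axis]] <- i
    args$drop <- FALSE
    do.call(`[`, args)
  }
  fwd <- idx(c(2:n, n))        # clamp: one-sided at upper border
  bwd <- idx(c(1, 1:(n - 1)))  # clamp: one-sided at lower border
  den <- array(2 * h, d)
  edge <- function(i, val) {
    args <- list(den)
    args[1 + seq_len(3)] <- lapply(d, seq_len)
    args[[1 + axis]] <- i
    args$value <- val
    do.call(`[<-`, args)
  }
  den <- edge(1L, h); den <- edge(n, h)
  (fwd - bwd) / den
}

#' Jacobian determinant of a deformation field
#'
#' For a field of displacements u(x), the encoded mapping is x + u(x); at
#' each voxel this computes the determinant of its 3x3 spatial gradient
#' (identity plus the displacement gradient), using central differences in
#' the interior and one-sided differences at grid borders. Values above 1
#' encode local expansion, below 1 contraction; non-positive determinants
#' signal a locally non-invertible mapping and are counted in a warning.
#'
#' @param field a \linkS4class{DeformationField} (displacements in mm).
#' @return A \linkS4class{VolumeMap} of determinants.
#' @examples
#' f <- DeformationField(array(0, c(4, 4, 4, 3)), voxelSize = 2)
#' range(voxelData(jacobianDeterminant(f)))  # identity mapping: all 1
#' @export
jacobianDeterminant <- function(field) {
  h <- field@voxelSize
  u <- field@data
  d <- dim(u)[1:3]
  if (any(d < 2L)) stop("grid must have >= 2 voxels along each axis")
  # g[[i]][[j]] = d u_i / d x_j
  g <- lapply(1:3, function(i) {
    ui <- array(u[, , , i], d)
    lapply(1:3, function(j) .gradAxis(ui, j, h))
  })
  # J = I + grad u; det expanded per voxel
  a11 <- 1 + g[[1]][[1]]; a12 <- g[[1]][[2]]; a13 <- g[[1]][[3]]
  a21 <- g[[2]][[1]]; a22 <- 1 + g[[2]][[2]]; a23 <- g[[2]][[3]]
  a31 <- g[[3]][[1]]; a32 <- g[[3]][[2]]; a33 <- 1 + g[[3]][[3]]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  nbad <- sum(det <= 0)
  if (nbad > 0) {
    warning(nbad, " voxels have non-positive Jacobian determinant ",
            "(locally non-invertible mapping)")
  }
  VolumeMap(det, voxelSize = h, origin = field@origin, name = "jacobian")
}

#' Modulate a Jacobian map by a tissue segmentation
#'
#' Voxelwise product of the determinant map and a tissue-probability map,
#' yielding the tissue-volume change map.
#'
#' @param jacobian,segmentation \linkS4class{VolumeMap}s of identical
#'   geometry.
#' @return A \linkS4class{VolumeMap}.
#' @export
modulate <- function(jacobian, segmentation) {
  stopIfGeometryMismatch(jacobian, segmentation, "jacobian and segmentation")
  VolumeMap(jacobian@data * segmentation@data, voxelSize = jacobian@voxelSize,
            origin = jacobian@origin, name = "modulated")
}

# 1-D convolution matrix with reflective boundary folding; rows index output
# voxels. Column sums are 1, so the volume total is preserved exactly.
.smoothMatrix1d <- function(n, sigmaVox) {
  r <- max(1L, ceiling(4 * sigmaVox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigmaVox^2))
  k <- k / sum(k)
  m <- matrix(0, n, n)
  for (off in seq(-r, r)) {
    j <- seq_len(n) + off
    # reflect indices about the grid edges (half-sample reflection)
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    j <- pmin(pmax(j, 1L), n)
    m[cbind(seq_len(n), j)] <- m[cbind(seq_len(n), j)] + k[off + r + 1L]
  }
  m
}

#' Gaussian smoothing of a volume
#'
#' Separable 3-D Gaussian convolution. The kernel width is given as full
#' width at half maximum in mm (the neuroimaging convention); the SD is
#' fwhm / sqrt(8 ln 2), converted to voxels. Boundaries are handled by
#' reflective padding, which preserves the volume total. \code{fwhmMm = 0}
#' returns the input unchanged.
#'
#' @param map a \linkS4class{VolumeMap}.
#' @param fwhmMm kernel full width at half maximum in mm (>= 0).
#' @return A smoothed \linkS4class{VolumeMap}.
#' @export
gaussianSmooth <- function(map, fwhmMm) {
  if (fwhmMm < 0) stop("fwhm must be >= 0")
  if (fwhmMm == 0) return(map)
  sigma <- fwhmMm / sqrt(8 * log(2)) / map@voxelSize
  d <- dim(map@data)
  a <- map@data
  for (axis in 1:3) {
    if (d[axis] > 1L) {
      m <- .smoothMatrix1d(d[axis], sigma)
      perm <- c(axis, setdiff(1:3, axis))
      ap <- aperm(a, perm)
      ap <- array(m %*% matrix(ap, d[axis]), dim(ap))
      a <- aperm(ap, order(perm))
    }
  }
  VolumeMap(a, voxelSize = map@voxelSize, origin = map@origin,
            name = map@name)
}

#' Mean regional volume change within an ROI
#'
#' In \code{mode = "jacobian"} the map is a raw Jacobian-modulated map
#' (no change = 1) and the mean of (value - 1) over ROI voxels is returned;
#' in \code{mode = "change"} the map already encodes signed change and its
#' plain mean is returned. The result is a signed fraction (0.01 = +1%).
#'
#' @param map a \linkS4class{VolumeMap}.
#' @param roi a binary \linkS4class{VolumeMap} of identical geometry.
#' @param mode "change" (default) or "jacobian".
#' @return signed fraction of volume change.
#' @export
roiGmvChange <- function(map, roi, mode = c("change", "jacobian")) {
  mode <- match.arg(mode)
  stopIfGeometryMismatch(map, roi, "map and roi")
  sel <- roi@data != 0
  if (!any(sel)) stop("empty ROI")
  v <- map@data[sel]
  if (mode == "jacobian") mean(v - 1) else mean(v)
}

#' Ellipsoidal brain-like analysis mask
#'
#' @param dims grid dimensions (length 3).
#' @param voxelSize voxel size mm.
#' @param fraction semi-axis length as a fraction of the half grid.
#' @return binary \linkS4class{VolumeMap}.
#' @export
makeEllipsoidMask <- function(dims = c(32, 32, 32), voxelSize = 2,
                              fraction = 0.85) {
  cx <- (dims + 1) / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  r2 <- ((g$x - cx[1]) / (fraction * dims[1] / 2))^2 +
        ((g$y - cx[2]) / (fraction * dims[2] / 2))^2 +
        ((g$z - cx[3]) / (fraction * dims[3] / 2))^2
  VolumeMap(array(as.numeric(r2 <= 1), dims), voxelSize = voxelSize,
            name = "mask")
}

#' Spherical binary mask (synthetic lesion / ROI)
#'
#' @param dims grid dimensions.
#' @param voxelSize voxel size mm.
#' @param center sphere centre in voxel coordinates.
#' @param radiusMm radius in mm.
#' @return binary \linkS4class{VolumeMap}.
#' @export
makeSphereMask <- function(dims, voxelSize, center, radiusMm) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  r2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  VolumeMap(array(as.numeric(r2 * voxelSize^2 <= radiusMm^2), dims),
            voxelSize = voxelSize, name = "sphere")
}

# generate k smooth, zero-mean, pairwise-orthogonal unit-variance spatial
# patterns inside a mask (the generator's orthogonality guarantee)
.makePatterns <- function(mask, k, fwhmMm = 12, seed = 1L) {
  sel <- mask@data != 0
  pats <- withSeed(seed, {
    lapply(seq_len(k), function(i) {
      raw <- VolumeMap(array(rnorm(length(mask@data)), dim(mask@data)),
                       voxelSize = mask@voxelSize, origin = mask@origin)
      gaussianSmooth(raw, fwhmMm)
    })
  })
  vecs <- vapply(pats, function(p) p@data[sel], numeric(sum(sel)))
  vecs <- scale(vecs, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(vecs))                       # orthonormal columns in-mask
  q <- sweep(q, 2, apply(q, 2, sd), "/")    # unit per-voxel SD ("amplitude 1")
  lapply(seq_len(k), function(i) {
    a <- array(0, dim(mask@data))
    a[sel] <- q[, i]
    VolumeMap(a, voxelSize = mask@voxelSize, origin = mask@origin,
              name = sprintf("pattern%d", i))
  })
}

#' Synthetic TBM dataset with embedded covariance patterns
#'
#' Each subject map is the loading-weighted sum of smooth, mask-orthogonal
#' ground-truth spatial patterns plus voxelwise Gaussian noise, optionally
#' followed by Gaussian smoothing. Pattern 1's subject loadings can be tied
#' to a behavioural vector at a configured correlation strength.
#'
#' @param nSubjects number of subjects.
#' @param mask binary \linkS4class{VolumeMap} defining the analysis volume.
#' @param nPatterns number of embedded patterns (default 2).
#' @param patternAmplitudes relative amplitude per pattern (default
#'   \code{2^-(0:(nPatterns-1))}: each successive pattern has half the
#'   amplitude, i.e. a quarter of the variance).
#' @param behavior optional per-subject behavioural vector.
#' @param behaviorCor target correlation in (-1, 1) between pattern-1
#'   loadings and \code{behavior} (0 = unlinked).
#' @param lesion optional per-subject lesion volumes; when \code{lesionCor}
#'   is nonzero, pattern-1 loadings also carry this signal.
#' @param lesionCor target correlation in (-1, 1) with \code{lesion};
#'   \code{|behaviorCor| + |lesionCor|} must leave positive residual
#'   variance.
#' @param noiseSd voxel noise SD relative to the unit per-voxel pattern
#'   amplitude (default 0.1).
#' @param fwhmMm post-hoc smoothing kernel (default 0, patterns themselves
#'   are already smooth).
#' @param seed integer seed.
#' @return list with \code{maps} (list of \linkS4class{VolumeMap}s) and
#'   \code{truth} (patterns, loadings matrix, noiseSd).
#' @export
synthTbmDataset <- function(nSubjects, mask, nPatterns = 2L,
                            patternAmplitudes = 2^-(seq_len(nPatterns) - 1),
                            behavior = NULL, behaviorCor = 0,
                            lesion = NULL, lesionCor = 0,
                            noiseSd = 0.1, fwhmMm = 0, seed = 1L) {
  if (abs(behaviorCor) >= 1 || abs(lesionCor) >= 1) {
    stop("requested loading correlation must lie in (-1, 1)")
  }
  resVar <- 1 - behaviorCor^2 - lesionCor^2
  if (resVar <= 0) {
    stop("behaviorCor and lesionCor jointly leave no residual variance")
  }
  patterns <- .makePatterns(mask, nPatterns, seed = deriveSeed(seed, 11))
  loadings <- withSeed(deriveSeed(seed, 12), {
    L <- matrix(rnorm(nSubjects * nPatterns), nSubjects, nPatterns)
    if ((!is.null(behavior) && behaviorCor != 0) ||
        (!is.null(lesion) && lesionCor != 0)) {
      sig <- rep(0, nSubjects)
      if (!is.null(behavior) && behaviorCor != 0) {
        sig <- sig + behaviorCor * as.numeric(scale(behavior))
      }
      if (!is.null(lesion) && lesionCor != 0) {
        sig <- sig + lesionCor * as.numeric(scale(lesion))
      }
      L[, 1] <- sig + sqrt(resVar) * L[, 1]
    }
    L
  })
  sel <- mask@data != 0
  pmat <- vapply(patterns, function(p) p@data[sel], numeric(sum(sel)))
  maps <- withSeed(deriveSeed(seed, 13), {
    lapply(seq_len(nSubjects), function(s) {
      v <- as.numeric(pmat %*% (loadings[s, ] * patternAmplitudes))
      if (noiseSd > 0) v <- v + rnorm(length(v), 0, noiseSd)
      a <- array(0, dim(mask@data))
      a[sel] <- v
      m <- VolumeMap(a, voxelSize = mask@voxelSize, origin = mask@origin,
                     name = sprintf("subject%02d", s))
      if (fwhmMm > 0) m <- gaussianSmooth(m, fwhmMm) else m
    })
  })
  list(maps = maps,
       truth = list(patterns = patterns, loadings = loadings,
                    amplitudes = patternAmplitudes, noiseSd = noiseSd))
}
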