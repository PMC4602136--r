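# Scaled-subprofile-model PCA of volume-change maps: masked data-matrix
# construction, two-way (row/column/grand-mean) centering, SVD into
# eigenimages / expression coefficients / variance fractions, and selection
# of components correlated with external variables.

#' Build the scans-by-voxels data matrix
#'
#' Stacks one row per input map, one column per in-mask voxel in fixed
#' raster (column-major) order. The in-mask voxel indices are attached as an
#' attribute so eigenimages and rows can be back-projected into volume
#' space.
#'
#' @param maps list of \linkS4class{VolumeMap}s sharing one geometry.
#' @param mask binary \linkS4class{VolumeMap} of the same geometry.
#' @return numeric matrix with attributes \code{voxelIndices},
#'   \code{maskDim}, \code{voxelSize} and \code{scanIds}.
#' @export
buildDataMatrix <- function(maps, mask) {
  idx <- which(mask@data != 0)
  if (length(idx) == 0L) stop("empty mask")
  for (m in maps) stopIfGeometryMismatch(m, mask, "maps and mask")
  x <- t(vapply(maps, function(m) m@data[idx], numeric(length(idx))))
  ids <- vapply(seq_along(maps), function(i) {
    nm <- maps[[i]]@name
    if (nzchar(nm)) nm else sprintf("scan%02d", i)
  }, character(1))
  structure(x, voxelIndices = as.integer(idx),
            maskDim = as.integer(dim(mask@data)),
            voxelSize = mask@voxelSize, scanIds = ids)
}

#' Back-project a voxel vector into volume space
#'
#' @param values numeric vector over in-mask voxels.
#' @param voxelIndices linear in-mask indices.
#' @param maskDim volume dimensions.
#' @param voxelSize voxel size mm.
#' @param name optional label.
#' @return \linkS4class{VolumeMap} with zeros outside the mask.
#' @export
backProject <- function(values, voxelIndices, maskDim, voxelSize = 2,
                        name = "") {
  a <- array(0, maskDim)
  a[voxelIndices] <- values
  VolumeMap(a, voxelSize = voxelSize, name = name)
}

#' Two-way centering of a scans-by-voxels matrix
#'
#' Subtracts from each element the mean of its column and the mean of its
#' row and adds back the grand mean, so that row, column and grand means of
#' the residual matrix all vanish.
#'
#' @param x numeric matrix (>= 2 rows and columns).
#' @return residual matrix of the same shape (attributes preserved).
#' @examples
#' doubleCenter(matrix(1:4, 2, byrow = TRUE))  # additive structure -> zeros
#' @export
doubleCenter <- function(x) {
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 rows and columns")
  r <- x - matrix(colMeans(x), nrow(x), ncol(x), byrow = TRUE) -
    matrix(rowMeans(x), nrow(x), ncol(x)) + mean(x)
  attributes(r) <- attributes(x)
  r
}

.checkCentered <- function(r, tol = 1e-6) {
  worst <- max(abs(c(rowMeans(r), colMeans(r), mean(r))))
  if (worst > tol * max(1, max(abs(r)))) {
    stop("input is not double-centered (worst residual mean = ",
         format(worst), "); apply doubleCenter() first")
  }
  invisible(TRUE)
}

#' SVD decomposition of a double-centred residual matrix
#'
#' Thin SVD with components in descending singular-value order. Eigenimages
#' (right singular vectors) and expression-coefficient columns (left
#' singular vectors) are unit-norm; the variance fraction of component i is
#' its squared singular value over the total. The sign convention makes the
#' largest-magnitude voxel of each eigenimage positive (the matching
#' coefficient column is flipped jointly); numerically null trailing
#' components are dropped.
#'
#' @param residual double-centred matrix from \code{\link{doubleCenter}}.
#' @param tol relative singular-value cutoff for null components.
#' @param signConvention "peakPositive" (default) or "none".
#' @return An \linkS4class{SSMDecomposition}.
#' @export
ssmDecompose <- function(residual, tol = 1e-10,
                         signConvention = c("peakPositive", "none")) {
  signConvention <- match.arg(signConvention)
  .checkCentered(residual)
  n <- nrow(residual); p <- ncol(residual)
  sv <- tryCatch({
    if (p > 4L * n) {
      # wide matrix: eigendecompose the small scan-covariance side
      g <- tcrossprod(residual)
      e <- eigen(g, symmetric = TRUE)
      d <- sqrt(pmax(e$values, 0))
      # null components show up at eigenvalue (not singular-value) scale here
      keep <- e$values > e$values[1] * tol
      u <- e$vectors[, keep, drop = FALSE]
      v <- crossprod(residual, u) %*% diag(1 / d[keep], sum(keep))
      list(d = d[keep], u = u, v = v)
    } else {
      s <- svd(residual)
      keep <- s$d > s$d[1] * tol
      list(d = s$d[keep], u = s$u[, keep, drop = FALSE],
           v = s$v[, keep, drop = FALSE])
    }
  }, error = function(e) {
    stop("SVD failed on a ", n, " x ", p, " residual matrix: ",
         conditionMessage(e))
  })
  eigenimages <- t(sv$v)              # components x voxels
  coefficients <- sv$u                # scans x components
  if (signConvention == "peakPositive") {
    for (i in seq_along(sv$d)) {
      peak <- which.max(abs(eigenimages[i, ]))
      if (eigenimages[i, peak] < 0) {
        eigenimages[i, ] <- -eigenimages[i, ]
        coefficients[, i] <- -coefficients[, i]
      }
    }
  }
  at <- attributes(residual)
  ids <- if (!is.null(at$scanIds)) at$scanIds else sprintf("scan%02d",
                                                           seq_len(n))
  new("SSMDecomposition",
      eigenimages = eigenimages,
      coefficients = coefficients,
      singularValues = sv$d,
      varianceFractions = sv$d^2 / sum(sv$d^2),
      voxelIndices = if (!is.null(at$voxelIndices)) at$voxelIndices
                     else seq_len(p),
      maskDim = if (!is.null(at$maskDim)) at$maskDim else c(p, 1L, 1L),
      voxelSize = if (!is.null(at$voxelSize)) at$voxelSize else 2,
      scanIds = ids)
}

#' Subject expression coefficients of one component
#'
#' @param decomp an \linkS4class{SSMDecomposition}.
#' @param component component index.
#' @return unit-norm per-scan coefficient vector (named by scan id).
#' @export
componentExpression <- function(decomp, component) {
  k <- nComponents(decomp)
  if (component < 1L || component > k) {
    stop("component index out of range 1..", k)
  }
  setNames(decomp@coefficients[, component], decomp@scanIds)
}

#' Back-project one eigenimage into volume space
#'
#' @inheritParams componentExpression
#' @return \linkS4class{VolumeMap} of voxel loadings, zeros outside mask.
#' @export
eigenimageVolume <- function(decomp, component) {
  k <- nComponents(decomp)
  if (component < 1L || component > k) {
    stop("component index out of range 1..", k)
  }
  backProject(decomp@eigenimages[component, ], decomp@voxelIndices,
              decomp@maskDim, decomp@voxelSize,
              name = sprintf("eigenimage%d", component))
}

#' Select components correlated with external variables
#'
#' Computes the Pearson correlation of every component's expression
#' coefficients with every external variable; a component is selected if any
#' |r| exceeds the Bonferroni-corrected critical correlation
#' \code{criticalR(n, alpha / m)}. The report mirrors the conventional
#' network-selection table layout (component, variance percent, variable, r,
#' selected flag).
#'
#' @param decomp an \linkS4class{SSMDecomposition}.
#' @param externals data.frame of per-scan variables (one row per scan).
#' @param alpha family-wise significance level (default 0.05).
#' @param m number of comparisons for the Bonferroni correction (default 8).
#' @param maxComponents restrict the screen to the leading components
#'   (default: all).
#' @return data.frame: component, variance_pct, variable, r, critical_r,
#'   selected.
#' @export
selectNetworks <- function(decomp, externals, alpha = 0.05, m = 8L,
                           maxComponents = nComponents(decomp)) {
  n <- nrow(decomp@coefficients)
  if (nrow(externals) != n) stop("externals must have one row per scan")
  rcrit <- criticalR(n, bonferroniAlpha(alpha, m)$alpha)
  comps <- seq_len(min(maxComponents, nComponents(decomp)))
  constant <- vapply(externals, function(x) all(is.na(x)) || sd(x) == 0,
                     logical(1))
  for (v in names(externals)[constant]) {
    warning("external variable '", v, "' is constant; correlation undefined")
  }
  rows <- list()
  for (k in comps) {
    co <- decomp@coefficients[, k]
    for (v in names(externals)) {
      if (constant[[v]]) {
        r <- NA_real_
      } else {
        r <- cor(co, externals[[v]], use = "complete.obs")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        component = k,
        variance_pct = 100 * decomp@varianceFractions[k],
        variable = v, r = r, critical_r = rcrit,
        selected = !is.na(r) && abs(r) > rcrit,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cumulative variance of selected components
#'
#' Aggregates per-component variance percentages (as printed, one decimal)
#' into the cumulative variance figure of the selection report.
#'
#' @param percents per-component variance percentages.
#' @return their sum, rounded to one decimal.
#' @examples
#' cumulativeVariance(c(19.9, 9.1, 8.1))  # 37.1
#' @export
cumulativeVariance <- function(percents) {
  round(sum(round(percents, 1)), 1)
}

#' Table-2-style network selection report
#'
#' Collapses the per-pair screen of \code{\link{selectNetworks}} to the
#' selected components with their significant correlates and appends the
#' cumulative variance of the selected set.
#'
#' @param screen output of \code{\link{selectNetworks}}.
#' @return list: \code{table} (selected rows) and
#'   \code{cumulativeVariancePct}.
#' @export
networkReport <- function(screen) {
  selComp <- unique(screen$component[screen$selected])
  tab <- screen[screen$component %in% selComp & screen$selected, ]
  pcts <- vapply(selComp, function(k) {
    round(screen$variance_pct[match(k, screen$component)], 1)
  }, numeric(1))
  list(table = tab, cumulativeVariancePct = cumulativeVariance(pcts))
}
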