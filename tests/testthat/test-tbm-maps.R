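test_that("jacobian determinant handles identity, translation and affine scaling", {
  dims <- c(8, 8, 8)
  idf <- DeformationField(array(0, c(dims, 3)), voxelSize = 2)
  expect_equal(voxelData(jacobianDeterminant(idf)),
               array(1, dims))
  tr <- DeformationField(array(rep(c(3, -2, 5), each = prod(dims)),
                               c(dims, 3)), voxelSize = 2)
  expect_equal(voxelData(jacobianDeterminant(tr)), array(1, dims))
  jd <- voxelData(jacobianDeterminant(affineScalingField(dims, 2, 0.02)))
  interior <- jd[2:7, 2:7, 2:7]
  expect_equal(max(abs(interior - 1.02^3)), 0, tolerance = 1e-6)
})

test_that("jacobian matches the matrix determinant for a general affine map", {
  # u(x) = (A - I) x for a non-diagonal invertible A
  A <- matrix(c(1.03, 0.01, 0, 0.02, 0.98, 0.01, 0, -0.01, 1.05), 3, 3)
  dims <- c(7, 7, 7); vox <- 2
  u <- array(0, c(dims, 3))
  for (i in 1:dims[1]) for (j in 1:dims[2]) for (k in 1:dims[3]) {
    x <- (c(i, j, k) - 1) * vox
    u[i, j, k, ] <- as.numeric((A - diag(3)) %*% x)
  }
  jd <- voxelData(jacobianDeterminant(DeformationField(u, vox)))
  expect_equal(max(abs(jd[2:6, 2:6, 2:6] - det(A))), 0, tolerance = 1e-6)
})

test_that("degenerate mappings are flagged by warning, not error", {
  # strong shrink folds space: determinant goes non-positive
  expect_warning(jacobianDeterminant(affineScalingField(c(6, 6, 6), 2, -1.5)),
                 "non-positive")
})

test_that("modulation is a voxelwise product with geometry checking", {
  j <- VolumeMap(array(1.05, c(4, 4, 4)), 2)
  seg <- VolumeMap(array(0.5, c(4, 4, 4)), 2)
  expect_equal(voxelData(modulate(j, seg))[1], 0.525)
  ones <- VolumeMap(array(1, c(4, 4, 4)), 2)
  expect_equal(voxelData(modulate(j, ones)), voxelData(j))
  zeros <- VolumeMap(array(0, c(4, 4, 4)), 2)
  expect_true(all(voxelData(modulate(j, zeros)) == 0))
  expect_error(modulate(j, VolumeMap(array(1, c(5, 4, 4)), 2)), "geometry")
})

test_that("gaussian smoothing preserves totals, constants and linearity", {
  set.seed(1)
  m <- VolumeMap(array(rnorm(11^3), c(11, 11, 11)), 2)
  expect_identical(gaussianSmooth(m, 0), m)
  sm <- gaussianSmooth(m, 12)
  expect_equal(sum(voxelData(sm)), sum(voxelData(m)), tolerance = 1e-6)
  cst <- VolumeMap(array(3.7, c(9, 9, 9)), 2)
  expect_equal(voxelData(gaussianSmooth(cst, 12)), voxelData(cst),
               tolerance = 1e-10)
  # linearity
  a <- VolumeMap(array(rnorm(7^3), c(7, 7, 7)), 2)
  b <- VolumeMap(array(rnorm(7^3), c(7, 7, 7)), 2)
  lhs <- gaussianSmooth(VolumeMap(2 * voxelData(a) - 3 * voxelData(b),
                                  2), 8)
  rhs <- 2 * voxelData(gaussianSmooth(a, 8)) -
    3 * voxelData(gaussianSmooth(b, 8))
  expect_equal(voxelData(lhs), rhs, tolerance = 1e-8)
  expect_error(gaussianSmooth(m, -1), ">= 0")
})

test_that("smoothing an impulse matches a dense convolution oracle", {
  dims <- c(11, 11, 11)
  a <- array(0, dims); a[6, 6, 6] <- 1
  sm <- voxelData(gaussianSmooth(VolumeMap(a, 2), 12))
  probes <- rbind(c(6, 6, 6), c(8, 6, 6), c(2, 3, 6))
  oracle <- denseSmoothAt(a, 12, 2, probes)
  got <- sm[probes]
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("ROI change extraction averages correctly in both modes", {
  dims <- c(4, 4, 4)
  roi <- VolumeMap(array(0, dims), 2)
  roi@data[1:2, 1, 1] <- 1
  jac <- VolumeMap(array(1.01, dims), 2)
  expect_equal(roiGmvChange(jac, roi, mode = "jacobian"), 0.01)
  chg <- VolumeMap(array(0, dims), 2)
  expect_equal(roiGmvChange(chg, roi, mode = "change"), 0)
  chg@data[1, 1, 1] <- 0.02; chg@data[2, 1, 1] <- 0.04
  expect_equal(roiGmvChange(chg, roi, mode = "change"), 0.03)
  expect_error(roiGmvChange(jac, VolumeMap(array(0, dims), 2)), "empty ROI")
})

test_that("synthetic TBM datasets are deterministic and respect loadings", {
  mask <- makeEllipsoidMask(c(12, 12, 12), 2)
  d1 <- synthTbmDataset(4, mask, nPatterns = 1, noiseSd = 0, seed = 9)
  d2 <- synthTbmDataset(4, mask, nPatterns = 1, noiseSd = 0, seed = 9)
  expect_identical(voxelData(d1$maps[[1]]), voxelData(d2$maps[[1]]))
  # noise 0, loadings +L/-L: maps are exact negatives
  L <- d1$truth$loadings
  m1 <- voxelData(d1$maps[[1]]); m2 <- voxelData(d1$maps[[2]])
  expect_equal(m1 / L[1, 1], m2 / L[2, 1], tolerance = 1e-10)
  expect_error(synthTbmDataset(4, mask, behaviorCor = 1.2,
                               behavior = rnorm(4)), "correlation")
})

test_that("configured loading-behavior correlation is realised in samples", {
  mask <- makeEllipsoidMask(c(8, 8, 8), 2)
  set.seed(3)
  beh <- rnorm(200)
  ds <- synthTbmDataset(200, mask, nPatterns = 1, behavior = beh,
                        behaviorCor = 0.8, noiseSd = 0, seed = 3)
  expect_equal(cor(ds$truth$loadings[, 1], beh), 0.8, tolerance = 0.1)
})
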