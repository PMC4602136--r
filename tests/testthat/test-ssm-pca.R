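test_that("data matrix construction and back-projection round-trip", {
  mask <- VolumeMap(array(0, c(4, 4, 4)), 2)
  mask@data[sample(1:64, 10)] <- 1
  maps <- lapply(1:3, function(i) {
    VolumeMap(array(rnorm(64), c(4, 4, 4)), 2, name = sprintf("m%d", i))
  })
  x <- buildDataMatrix(maps, mask)
  expect_equal(dim(x), c(3L, 10L))
  # back-projection reproduces the masked map
  v <- backProject(x[2, ], attr(x, "voxelIndices"), attr(x, "maskDim"), 2)
  expect_equal(voxelData(v)[mask@data != 0],
               voxelData(maps[[2]])[mask@data != 0])
  expect_true(all(voxelData(v)[mask@data == 0] == 0))
  expect_error(buildDataMatrix(maps, VolumeMap(array(0, c(4, 4, 4)), 2)),
               "empty mask")
  expect_error(buildDataMatrix(maps, VolumeMap(array(1, c(5, 4, 4)), 2)),
               "geometry")
})

test_that("double centering matches the formula and is idempotent", {
  expect_equal(doubleCenter(matrix(c(1, 3, 2, 4), 2)),
               matrix(0, 2, 2))
  r <- doubleCenter(matrix(c(1, 4, 2, 3), 2))
  expect_equal(r, matrix(c(-0.5, 0.5, 0.5, -0.5), 2))
  expect_equal(doubleCenter(r), r)
  set.seed(4)
  x <- matrix(rnorm(6 * 20), 6, 20)
  rc <- doubleCenter(x)
  expect_lt(max(abs(rowMeans(rc))), 1e-10)
  expect_lt(max(abs(colMeans(rc))), 1e-10)
  expect_lt(abs(mean(rc)), 1e-10)
  expect_error(doubleCenter(matrix(1, 1, 5)), ">= 2")
})

test_that("decomposition satisfies orthonormality, range and variance invariants", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(3:8, 1); p <- sample(10:40, 1)
    d <- ssmDecompose(doubleCenter(matrix(rnorm(n * p), n, p)))
    k <- nComponents(d)
    expect_lte(k, n - 1)
    gu <- crossprod(d@coefficients)
    gv <- tcrossprod(d@eigenimages)
    expect_equal(gu, diag(k), tolerance = 1e-8)
    expect_equal(gv, diag(k), tolerance = 1e-8)
    expect_true(all(abs(d@coefficients) <= 1 + 1e-12))
    expect_equal(sum(varianceFractions(d)), 1, tolerance = 1e-8)
    expect_false(is.unsorted(rev(singularValues(d))))
  }
})

test_that("decomposition reconstructs the residual and matches a dense eigen oracle", {
  set.seed(11)
  r <- doubleCenter(matrix(rnorm(10 * 200), 10, 200))
  d <- ssmDecompose(r)
  recon <- d@coefficients %*% (singularValues(d) * d@eigenimages)
  expect_equal(max(abs(recon - r)) / max(abs(r)), 0, tolerance = 1e-8)
  # oracle: eigenvalues of the scan-covariance matrix R R^T equal sigma^2
  ev <- eigen(tcrossprod(r), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(singularValues(d)^2, ev[seq_len(nComponents(d))],
               tolerance = 1e-8)
  # rank-1 residual
  u <- c(1, -1, 0, 0); v <- rnorm(30)
  r1 <- doubleCenter(outer(u, v))
  d1 <- ssmDecompose(r1)
  expect_equal(nComponents(d1), 1L)
  expect_equal(varianceFractions(d1), 1)
})

test_that("expression coefficients are unit-norm, zero-mean and scan-equivariant", {
  set.seed(12)
  x <- matrix(rnorm(6 * 50), 6, 50)
  d <- ssmDecompose(doubleCenter(x))
  co <- componentExpression(d, 1)
  expect_equal(sum(co^2), 1, tolerance = 1e-10)
  expect_equal(sum(co), 0, tolerance = 1e-10)
  expect_error(componentExpression(d, 99), "out of range")
  # swapping two scans swaps their coefficients
  xs <- x[c(2, 1, 3:6), ]
  ds <- ssmDecompose(doubleCenter(xs))
  cs <- componentExpression(ds, 1)
  s <- sign(sum(co[c(2, 1, 3:6)] * cs))
  expect_equal(unname(co[c(2, 1, 3:6)]) * s, unname(cs), tolerance = 1e-8)
})

test_that("network screen selects exactly the externally-correlated component", {
  set.seed(13)
  d <- ssmDecompose(doubleCenter(matrix(rnorm(8 * 60), 8, 60)))
  self <- data.frame(v = componentExpression(d, 2))
  screen <- selectNetworks(d, self, alpha = 0.05, m = 8)
  hit <- screen[screen$component == 2, ]
  expect_equal(hit$r, 1, tolerance = 1e-10)
  expect_true(hit$selected)
  # rank-2 decomposition; an external orthogonal to both coefficient
  # vectors (and the constant) selects nothing
  q <- qr.Q(qr(cbind(1, matrix(rnorm(8 * 3), 8, 3))))
  u1 <- q[, 2]; u2 <- q[, 3]; orthov <- q[, 4]
  x2 <- outer(u1, rnorm(60)) + 0.5 * outer(u2, rnorm(60))
  d2 <- ssmDecompose(doubleCenter(x2))
  s2 <- selectNetworks(d2, data.frame(v = orthov), alpha = 0.05, m = 8)
  expect_false(any(s2$selected))
  expect_warning(selectNetworks(d, data.frame(v = rep(1, 8))), "constant")
})

test_that("variance aggregation reproduces printed cumulative figures", {
  expect_equal(cumulativeVariance(c(19.9, 9.1, 8.1)), 37.1)
  expect_equal(cumulativeVariance(numeric(0)), 0)
})
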