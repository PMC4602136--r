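test_that("percentile height thresholds isolate the correct tails", {
  # values 1..100 laid into a 100-voxel grid, fully in-mask
  a <- array(0, c(10, 10, 1)); a[] <- 1:100
  img <- VolumeMap(array(c(a), c(10, 10, 1)), 2)
  mask <- VolumeMap(array(1, c(10, 10, 1)), 2)
  th <- thresholdEigenimage(img, mask, 1, 99)
  # brute-force percentiles of the enumerated set (linear interpolation)
  qlow <- unname(quantile(1:100, 0.01)); qhigh <- unname(quantile(1:100, 0.99))
  expect_equal(sum(voxelData(th$low)), sum(1:100 <= qlow))
  expect_equal(sum(voxelData(th$high)), sum(1:100 >= qhigh))
  expect_equal(unname(th$thresholds), c(qlow, qhigh))
  # symmetric values give equal tail counts
  sym <- VolumeMap(array(c(-(50:1), 1:50), c(10, 10, 1)), 2)
  ts <- thresholdEigenimage(sym, mask, 5, 95)
  expect_equal(sum(voxelData(ts$low)), sum(voxelData(ts$high)))
  # constant image: empty tails with warning
  expect_warning(tc <- thresholdEigenimage(
    VolumeMap(array(1, c(10, 10, 1)), 2), mask), "constant")
  expect_equal(sum(voxelData(tc$low)) + sum(voxelData(tc$high)), 0)
})

test_that("extent threshold discards small components and volumes use voxel size", {
  a <- array(0, c(8, 8, 8))
  a[1:31] <- 1                      # 31-voxel blob (one contiguous column run)
  small <- connectedClusters(VolumeMap(a, 2), kMin = 32)
  expect_equal(nrow(small$table), 0L)
  a[32] <- 1                        # now 32 voxels
  big <- connectedClusters(VolumeMap(a, 2), kMin = 32, tail = "low")
  expect_equal(big$table$size_vox, 32L)
  expect_equal(big$table$volume_cc, 0.256)   # 32 * 0.008 cc
})

test_that("corner-touching blobs split under 6- but merge under 26-connectivity", {
  a <- array(0, c(5, 5, 5))
  a[2, 2, 2] <- 1
  a[3, 3, 3] <- 1                  # touches only at a corner
  c6 <- connectedClusters(VolumeMap(a, 2), connectivity = 6, kMin = 1)
  c26 <- connectedClusters(VolumeMap(a, 2), connectivity = 26, kMin = 1)
  expect_equal(nrow(c6$table), 2L)
  expect_equal(nrow(c26$table), 1L)
  # edge-touching merges at 18 but not 6
  b <- array(0, c(5, 5, 5)); b[2, 2, 2] <- 1; b[3, 3, 2] <- 1
  expect_equal(nrow(connectedClusters(VolumeMap(b, 2), connectivity = 6,
                                      kMin = 1)$table), 2L)
  expect_equal(nrow(connectedClusters(VolumeMap(b, 2), connectivity = 18,
                                      kMin = 1)$table), 1L)
})

test_that("labeling agrees with a brute-force flood fill on random grids", {
  set.seed(14)
  for (i in 1:30) {
    a <- array(rbinom(8^3, 1, 0.3), c(8, 8, 8))
    for (conn in c(6, 26)) {
      got <- connectedClusters(VolumeMap(a, 2), connectivity = conn,
                               kMin = 1)
      oracle <- floodLabels(a, conn)
      # same partition: compare sorted component sizes and same membership
      expect_equal(sort(got$table$size_vox),
                   sort(as.integer(table(oracle[oracle > 0]))))
      gl <- voxelData(got$labels)
      relab <- paste(gl[a != 0], oracle[a != 0])
      expect_equal(length(unique(relab)), max(oracle))
    }
  }
})

test_that("lesion density maps apply the strict >20% rule", {
  dims <- c(4, 4, 4)
  mk <- function(on) {
    v <- VolumeMap(array(0, dims), 2)
    v@data[on] <- 1
    v
  }
  # voxel 1 lesioned in 2/8 subjects (0.25 > 0.2), voxel 2 in 1/8 (0.125)
  lesions <- c(lapply(1:2, function(i) mk(1)), list(mk(2)),
               lapply(1:5, function(i) mk(3)))
  ld <- lesionDensity(lesions, 0.20)
  expect_equal(voxelData(ld$density)[1], 0.25)
  expect_equal(voxelData(ld$thresholded)[1], 1)
  expect_equal(voxelData(ld$thresholded)[2], 0)
  # threshold 0 gives the union
  u <- lesionDensity(lesions, 0)
  expect_equal(which(voxelData(u$thresholded) != 0), c(1L, 2L, 3L))
  expect_error(lesionDensity(list()), "at least one")
})

test_that("lesion volume sums binary voxels times voxel volume", {
  dims <- c(6, 6, 6)
  v <- VolumeMap(array(0, dims), 2)
  expect_equal(lesionVolume(v), 0)
  v@data[1:125] <- 1
  expect_equal(lesionVolume(v), 1.0)         # 125 x 0.008 cc
  v@data[1] <- 0.5
  expect_error(lesionVolume(v), "binary")
})

test_that("overlap volumetrics match the printed-percentage arithmetic", {
  pp <- overlapPercentages(7.10, 105.7, 10.9)
  expect_equal(pp$pct_of_lesion, 6.7)
  p2 <- overlapPercentages(8.7, 239.7, 10.9)
  expect_equal(p2$pct_of_lesion, 3.6)
  expect_true(is.na(overlapPercentages(0, 0, 1)$pct_of_lesion))
})

test_that("cluster/lesion overlap is symmetric and bounded", {
  dims <- c(6, 6, 6)
  lab <- array(0, dims); lab[1:20] <- 1
  clusters <- list(
    table = data.frame(tail = "low", cluster = 1L, size_vox = 20L,
                       volume_cc = 20 * 0.008, peak_value = NA_real_,
                       peak_x_mm = NA_real_, peak_y_mm = NA_real_,
                       peak_z_mm = NA_real_, stringsAsFactors = FALSE),
    labels = list(low = VolumeMap(lab, 2)))
  les <- VolumeMap(array(0, dims), 2); les@data[15:40] <- 1
  dens <- list(g = lesionDensity(list(les), 0))
  ov <- overlapVolumetrics(clusters, dens)
  # overlap voxels 15..20 -> 6 voxels
  expect_equal(ov$overlap_cc, 6 * 0.008)
  expect_lte(ov$overlap_cc, min(ov$cluster_cc, ov$lesion_cc))
  # symmetric: intersecting the other way gives the same cc
  lab2 <- array(0, dims); lab2[15:40] <- 1
  clusters2 <- list(
    table = data.frame(tail = "low", cluster = 1L, size_vox = 26L,
                       volume_cc = 26 * 0.008, peak_value = NA_real_,
                       peak_x_mm = NA_real_, peak_y_mm = NA_real_,
                       peak_z_mm = NA_real_, stringsAsFactors = FALSE),
    labels = list(low = VolumeMap(lab2, 2)))
  les2 <- VolumeMap(array(0, dims), 2); les2@data[1:20] <- 1
  ov2 <- overlapVolumetrics(clusters2, list(g = lesionDensity(list(les2), 0)))
  expect_equal(ov2$overlap_cc, ov$overlap_cc)
  # disjoint -> all zeros; nested -> 100% of cluster
  lesFar <- VolumeMap(array(0, dims), 2); lesFar@data[100:120] <- 1
  ovd <- overlapVolumetrics(clusters, list(g = lesionDensity(list(lesFar), 0)))
  expect_equal(ovd$overlap_cc, 0)
  expect_equal(ovd$pct_of_lesion, 0)
  lesAll <- VolumeMap(array(0, dims), 2); lesAll@data[1:60] <- 1
  ovn <- overlapVolumetrics(clusters, list(g = lesionDensity(list(lesAll), 0)))
  expect_equal(ovn$pct_of_cluster, 100.0)
})

test_that("low-tail cluster mass respects the percentile bound", {
  set.seed(15)
  img <- VolumeMap(array(rnorm(16^3), c(16, 16, 16)), 2)
  mask <- makeEllipsoidMask(c(16, 16, 16), 2)
  cl <- clusterEigenimage(img, mask, lowPct = 10, highPct = 90, kMin = 1)
  nIn <- sum(voxelData(mask) != 0)
  lowSizes <- cl$table$size_vox[cl$table$tail == "low"]
  expect_lte(sum(lowSizes), nIn * 10 / 100 + 1)
})
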