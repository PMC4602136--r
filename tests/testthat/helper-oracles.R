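# Independent oracles used across the suite; deliberately naive
# implementations, kept separate from the package's own code paths.

# brute-force flood-fill connected-component labeling
floodLabels <- function(arr, connectivity) {
  d <- dim(arr)
  lab <- array(0L, d)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  s <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[switch(as.character(connectivity),
                      "6" = s == 1, "18" = s >= 1 & s <= 2, "26" = s >= 1), ]
  cur <- 0L
  for (i in which(arr != 0)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      co <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        nb <- c(co[1] + offs$dx[r], co[2] + offs$dy[r], co[3] + offs$dz[r])
        if (all(nb >= 1) && all(nb <= d)) {
          li <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
          if (arr[li] != 0 && lab[li] == 0L) {
            lab[li] <- cur
            queue <- c(queue, li)
          }
        }
      }
    }
  }
  lab
}

# dense 3-D Gaussian convolution evaluated at selected probe voxels, with
# half-sample reflective boundary handling
denseSmoothAt <- function(a, fwhmMm, voxelMm, probes) {
  sigma <- fwhmMm / sqrt(8 * log(2)) / voxelMm
  r <- max(1L, ceiling(4 * sigma))
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    i <- ifelse(i > n, 2L * n + 1L - i, i)
    pmin(pmax(i, 1L), n)
  }
  d <- dim(a)
  apply(probes, 1, function(p) {
    s <- 0
    for (ox in -r:r) for (oy in -r:r) for (oz in -r:r) {
      s <- s + k1[ox + r + 1] * k1[oy + r + 1] * k1[oz + r + 1] *
        a[refl(p[1] + ox, d[1]), refl(p[2] + oy, d[2]), refl(p[3] + oz, d[3])]
    }
    s
  })
}

# uniform affine scaling field u(x) = s * x (x in mm from the grid origin)
affineScalingField <- function(dims, voxelMm, s) {
  u <- array(0, c(dims, 3))
  for (i in seq_len(dims[1])) u[i, , , 1] <- s * (i - 1) * voxelMm
  for (j in seq_len(dims[2])) u[, j, , 2] <- s * (j - 1) * voxelMm
  for (k in seq_len(dims[3])) u[, , k, 3] <- s * (k - 1) * voxelMm
  DeformationField(u, voxelSize = voxelMm)
}
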