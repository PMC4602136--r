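# Cluster delineation from eigenimages (percentile height threshold +
# extent threshold), lesion-density maps, and cluster/lesion overlap
# volumetrics.

#' Percentile height threshold of an eigenimage
#'
#' Percentiles are computed over in-mask voxel values only, with linear
#' interpolation between order statistics. The low-tail map keeps voxels
#' with value <= P(lowPct), the high-tail map voxels >= P(highPct)
#' (boundary values inclusive, so the percentile voxel itself survives).
#' A constant image yields empty tails with a warning.
#'
#' @param image \linkS4class{VolumeMap} of voxel loadings.
#' @param mask binary \linkS4class{VolumeMap}, same geometry.
#' @param lowPct,highPct percentiles in (0, 100), low < high (default 1/99).
#' @return list: \code{low} and \code{high} binary \linkS4class{VolumeMap}s
#'   and \code{thresholds} (the two cut values).
#' @export
thresholdEigenimage <- function(image, mask, lowPct = 1, highPct = 99) {
  stopIfGeometryMismatch(image, mask, "image and mask")
  if (!(lowPct > 0 && lowPct < highPct && highPct < 100)) {
    stop("need 0 < lowPct < highPct < 100")
  }
  sel <- mask@data != 0
  if (!any(sel)) stop("empty mask")
  v <- image@data[sel]
  if (max(v) - min(v) < .Machine$double.eps * max(1, abs(max(v)))) {
    warning("constant image: both tails empty")
    empty <- VolumeMap(array(0, dim(image@data)), image@voxelSize,
                       image@origin)
    return(list(low = empty, high = empty,
                thresholds = c(low = NA_real_, high = NA_real_)))
  }
  q <- quantile(v, probs = c(lowPct, highPct) / 100, names = FALSE, type = 7)
  lowA <- array(0, dim(image@data)); highA <- lowA
  lowA[sel & image@data <= q[1]] <- 1
  highA[sel & image@data >= q[2]] <- 1
  list(low = VolumeMap(lowA, image@voxelSize, image@origin, "low tail"),
       high = VolumeMap(highA, image@voxelSize, image@origin, "high tail"),
       thresholds = c(low = q[1], high = q[2]))
}

# neighbourhood offsets for 6 (faces), 18 (faces+edges) or 26 (full cube)
# connectivity; only the lexicographically positive half is returned
.halfOffsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  s <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = s == 1, "18" = s >= 1 & s <= 2, "26" = s >= 1,
                 stop("connectivity must be 6, 18 or 26"))
  g <- g[keep, ]
  g[g$dz > 0 | (g$dz == 0 & g$dy > 0) |
      (g$dz == 0 & g$dy == 0 & g$dx > 0), ]
}

#' Connected-component clusters of a binary map
#'
#' Labels connected components of the active voxels under the chosen voxel
#' connectivity, discards components smaller than the extent threshold
#' \code{kMin}, and reports the survivors sorted by size (descending) with
#' their volume in cc and, when a value map is supplied, the peak
#' (largest-magnitude) voxel value and its mm coordinate.
#'
#' @param binary binary \linkS4class{VolumeMap}.
#' @param values optional \linkS4class{VolumeMap} of the underlying voxel
#'   values (e.g. the eigenimage) for peak reporting.
#' @param connectivity 6, 18 or 26 (default 18).
#' @param kMin extent threshold in voxels (default 32).
#' @param tail label stored in the table's \code{tail} column.
#' @return list: \code{table} (data.frame: tail, cluster, size_vox,
#'   volume_cc, peak_value, peak_x/y/z_mm) and \code{labels} (integer
#'   \linkS4class{VolumeMap}; 0 outside clusters).
#' @export
connectedClusters <- function(binary, values = NULL, connectivity = 18L,
                              kMin = 32L, tail = NA_character_) {
  if (kMin < 1L) stop("kMin must be >= 1")
  d <- dim(binary@data)
  act <- which(binary@data != 0)
  labArr <- array(0L, d)
  tab <- data.frame(tail = character(0), cluster = integer(0),
                    size_vox = integer(0), volume_cc = numeric(0),
                    peak_value = numeric(0), peak_x_mm = numeric(0),
                    peak_y_mm = numeric(0), peak_z_mm = numeric(0),
                    stringsAsFactors = FALSE)
  if (length(act) == 0L) {
    return(list(table = tab,
                labels = VolumeMap(labArr, binary@voxelSize, binary@origin)))
  }
  vid <- array(0L, d); vid[act] <- seq_along(act)
  co <- arrayInd(act, d)
  offsets <- .halfOffsets(connectivity)
  edges <- list()
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    nb <- cbind(co[, 1] + off$dx, co[, 2] + off$dy, co[, 3] + off$dz)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nbid <- vid[nb[ok, , drop = FALSE]]
    src <- seq_along(act)[ok]
    conn <- nbid > 0L
    if (any(conn)) edges[[length(edges) + 1L]] <- cbind(src[conn], nbid[conn])
  }
  g <- igraph::make_empty_graph(n = length(act), directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  sizes <- comp$csize
  keep <- which(sizes >= kMin)
  if (length(keep) > 0L) {
    ord <- keep[order(sizes[keep], decreasing = TRUE)]
    vv <- (binary@voxelSize / 10)^3
    rows <- vector("list", length(ord))
    for (i in seq_along(ord)) {
      memb <- act[comp$membership == ord[i]]
      labArr[memb] <- i
      pk <- c(NA_real_, NA_real_, NA_real_); pv <- NA_real_
      if (!is.null(values)) {
        v <- values@data[memb]
        j <- which.max(abs(v))
        pv <- v[j]
        pk <- (arrayInd(memb[j], d) - 1) * binary@voxelSize + binary@origin
      }
      rows[[i]] <- data.frame(tail = tail, cluster = i,
                              size_vox = length(memb),
                              volume_cc = length(memb) * vv,
                              peak_value = pv, peak_x_mm = pk[1],
                              peak_y_mm = pk[2], peak_z_mm = pk[3],
                              stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
  }
  list(table = tab,
       labels = VolumeMap(labArr, binary@voxelSize, binary@origin, "labels"))
}

#' Delineate network clusters from an eigenimage
#'
#' Applies the percentile height threshold and the extent threshold to both
#' tails of an eigenimage and returns one combined cluster table.
#'
#' @inheritParams thresholdEigenimage
#' @inheritParams connectedClusters
#' @return list: \code{table} (both tails, cluster ids "1low", "1high", ...),
#'   \code{labels} named list of the two label volumes, \code{thresholds}.
#' @export
clusterEigenimage <- function(image, mask, lowPct = 1, highPct = 99,
                              connectivity = 18L, kMin = 32L) {
  th <- thresholdEigenimage(image, mask, lowPct, highPct)
  lo <- connectedClusters(th$low, values = image, connectivity = connectivity,
                          kMin = kMin, tail = "low")
  hi <- connectedClusters(th$high, values = image,
                          connectivity = connectivity, kMin = kMin,
                          tail = "high")
  list(table = rbind(lo$table, hi$table),
       labels = list(low = lo$labels, high = hi$labels),
       thresholds = th$thresholds)
}

#' Subgroup lesion-density map
#'
#' Per-voxel fraction of subjects whose lesion covers the voxel, binarised
#' by a strict density threshold (default > 20 percent).
#'
#' @param lesions list of binary \linkS4class{VolumeMap}s (one per subject).
#' @param threshold density threshold; voxels with fraction strictly above
#'   it survive (default 0.20).
#' @param subgroup optional subgroup label.
#' @return list: \code{density} (fractional map), \code{thresholded}
#'   (binary map), \code{volume_cc} of the thresholded map, \code{subgroup}.
#' @export
lesionDensity <- function(lesions, threshold = 0.20, subgroup = NA_character_) {
  if (length(lesions) < 1L) stop("need at least one lesion mask")
  ref <- lesions[[1]]
  acc <- array(0, dim(ref@data))
  for (l in lesions) {
    stopIfGeometryMismatch(l, ref, "lesion masks")
    acc <- acc + (l@data != 0)
  }
  dens <- acc / length(lesions)
  thr <- array(as.numeric(dens > threshold), dim(ref@data))
  list(density = VolumeMap(dens, ref@voxelSize, ref@origin, "lesion density"),
       thresholded = VolumeMap(thr, ref@voxelSize, ref@origin,
                               "thresholded density"),
       volume_cc = sum(thr) * (ref@voxelSize / 10)^3,
       subgroup = subgroup)
}

#' Volume of a binary lesion mask in cc
#'
#' @param lesion binary \linkS4class{VolumeMap} (values 0/1 only).
#' @return lesioned volume in cc (voxel count times voxel volume).
#' @export
lesionVolume <- function(lesion) {
  v <- lesion@data
  if (!all(v %in% c(0, 1))) stop("lesion mask must be binary (0/1)")
  sum(v) * (lesion@voxelSize / 10)^3
}

#' Overlap percentages from raw volumes
#'
#' Desk arithmetic of the overlap report: percent of the lesion-density map
#' falling on the cluster and percent of the cluster affected by the lesion,
#' rounded to one decimal as printed (full precision also returned).
#'
#' @param overlapCc,lesionCc,clusterCc volumes in cc.
#' @return list: pct_of_lesion, pct_of_cluster (rounded), and their
#'   full-precision counterparts; NA where a denominator is zero.
#' @export
overlapPercentages <- function(overlapCc, lesionCc, clusterCc) {
  pl <- if (lesionCc > 0) 100 * overlapCc / lesionCc else NA_real_
  pc <- if (clusterCc > 0) 100 * overlapCc / clusterCc else NA_real_
  list(pct_of_lesion = round(pl, 1), pct_of_cluster = round(pc, 1),
       pct_of_lesion_full = pl, pct_of_cluster_full = pc)
}

#' Cluster / lesion-density overlap volumetrics
#'
#' Intersects every cluster (from a label volume) with every subgroup
#' thresholded lesion-density map and reports raw overlap volume plus both
#' percentage views.
#'
#' @param clusters result of \code{\link{clusterEigenimage}} (or
#'   \code{\link{connectedClusters}}).
#' @param densities named list of \code{\link{lesionDensity}} results.
#' @return data.frame: subgroup, tail, cluster, overlap_cc, lesion_cc,
#'   cluster_cc, pct_of_lesion, pct_of_cluster.
#' @export
overlapVolumetrics <- function(clusters, densities) {
  labs <- clusters$labels
  if (is(labs, "VolumeMap")) labs <- list(all = labs)
  tab <- clusters$table
  rows <- list()
  for (sg in names(densities)) {
    dm <- densities[[sg]]$thresholded
    vv <- (dm@voxelSize / 10)^3
    lesCc <- densities[[sg]]$volume_cc
    for (i in seq_len(nrow(tab))) {
      lv <- if (!is.null(labs[[tab$tail[i]]])) labs[[tab$tail[i]]] else
        labs[[1]]
      stopIfGeometryMismatch(lv, dm, "labels and density map")
      ov <- sum(lv@data == tab$cluster[i] & dm@data != 0) * vv
      pp <- overlapPercentages(ov, lesCc, tab$volume_cc[i])
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = sg, tail = tab$tail[i], cluster = tab$cluster[i],
        overlap_cc = ov, lesion_cc = lesCc, cluster_cc = tab$volume_cc[i],
        pct_of_lesion = pp$pct_of_lesion,
        pct_of_cluster = pp$pct_of_cluster, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(subgroup = character(0), tail = character(0),
                      cluster = integer(0), overlap_cc = numeric(0),
                      lesion_cc = numeric(0), cluster_cc = numeric(0),
                      pct_of_lesion = numeric(0),
                      pct_of_cluster = numeric(0)))
  }
  do.call(rbind, rows)
}
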