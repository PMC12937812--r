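# Neighbor offsets for 6- (face) and 18- (face+edge) connectivity.
neighbor_offsets <- function(connectivity = 6) {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  man <- abs(d$dx) + abs(d$dy) + abs(d$dz)
  if (connectivity == 6) d[man == 1, ]
  else if (connectivity == 18) d[man <= 2, ]
  else stop("connectivity must be 6 or 18")
}

# Label connected components of a logical 3D array.
label_components <- function(mask3d, connectivity = 6) {
  g <- dim(mask3d)
  off <- neighbor_offsets(connectivity)
  labels <- array(0L, g)
  cur <- 0L
  idx_all <- which(mask3d)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      z <- (v - 1L) %/% (g[1] * g[2]) + 1L
      rem <- (v - 1L) %% (g[1] * g[2])
      y <- rem %/% g[1] + 1L
      x <- rem %% g[1] + 1L
      nx <- x + off$dx; ny <- y + off$dy; nz <- z + off$dz
      ok <- nx >= 1 & nx <= g[1] & ny >= 1 & ny <= g[2] & nz >= 1 & nz <= g[3]
      nb <- (nz[ok] - 1L) * g[1] * g[2] + (ny[ok] - 1L) * g[1] + nx[ok]
      nb <- nb[mask3d[nb] & labels[nb] == 0L]
      labels[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Cluster-extent thresholding of a statistical map
#'
#' Voxels whose (one-sided by default) p value falls below `p_voxel` are
#' grouped into connected clusters (face connectivity by default) and
#' clusters smaller than `k` voxels are discarded — uncorrected-threshold
#' plus minimum-extent inference. The extent `k` depends on the search
#' volume and smoothness and is taken as an input, with the study's values
#' (17 tapping, 16 imagery, 15 covariate) as reference presets.
#'
#' @param stat_map a `stat_map` with known `df`.
#' @param p_voxel voxelwise threshold (default 0.001).
#' @param k minimum cluster extent in voxels.
#' @param sided `"one"` (positive t, default) or `"two"` (|t|).
#' @param connectivity 6 (face, default) or 18 (face + edge).
#' @return object of class `cluster_table`: data.frame with `cluster_id`,
#'   `size_voxels`, `peak_t`, `peak_x`, `peak_y`, `peak_z`; the suprathreshold
#'   label array is attached as attribute `"labels"` and the threshold as
#'   `"threshold"`.
#' @export
cluster_threshold <- function(stat_map, p_voxel = 0.001, k = 15,
                              sided = c("one", "two"), connectivity = 6) {
  sided <- match.arg(sided)
  stopifnot(inherits(stat_map, "stat_map"), !is.null(stat_map$grid_shape))
  tcrit <- if (stat_map$df <= 0) Inf  # no residual df: nothing can survive
           else if (sided == "one") stats::qt(1 - p_voxel, stat_map$df)
           else stats::qt(1 - p_voxel / 2, stat_map$df)
  tv <- stat_map$t
  sup <- if (sided == "one") !is.na(tv) & tv > tcrit else !is.na(tv) & abs(tv) > tcrit
  mask3d <- array(sup, stat_map$grid_shape)
  labels <- label_components(mask3d, connectivity)
  tab <- list()
  keep_labels <- array(0L, stat_map$grid_shape)
  out_id <- 0L
  for (lb in seq_len(max(labels))) {
    vox <- which(labels == lb)
    if (length(vox) < k) next
    out_id <- out_id + 1L
    keep_labels[vox] <- out_id
    crit <- if (sided == "one") tv[vox] else abs(tv)[vox]
    peak <- vox[which.max(crit)]
    pc <- arrayInd(peak, stat_map$grid_shape)
    tab[[out_id]] <- data.frame(cluster_id = out_id, size_voxels = length(vox),
                                peak_t = tv[peak], peak_x = pc[1],
                                peak_y = pc[2], peak_z = pc[3])
  }
  tab <- if (length(tab)) do.call(rbind, tab) else
    data.frame(cluster_id = integer(0), size_voxels = integer(0),
               peak_t = numeric(0), peak_x = integer(0), peak_y = integer(0),
               peak_z = integer(0))
  tab <- tab[order(-tab$size_voxels), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, labels = keep_labels,
            threshold = list(p = p_voxel, k = k, t = tcrit, sided = sided,
                             connectivity = connectivity),
            class = c("cluster_table", "data.frame"))
}

#' ROI summary and correlation with improvement
#'
#' The ROI mean per subject is the mean contrast estimate over the cluster's
#' voxels; it is then rank-correlated (Spearman) with the improvement
#' scores.
#'
#' @param contrast_maps list of `contrast_map`s or voxels x subjects matrix.
#' @param cluster_voxels linear voxel indices of the ROI (nonempty).
#' @param delta_rmse per-subject improvement scores.
#' @return list with `roi_means` and `correlation` (a [spearman_rho()]
#'   result).
#' @export
roi_summary <- function(contrast_maps, cluster_voxels, delta_rmse) {
  if (!length(cluster_voxels)) stop("cluster is empty")
  M <- maps_matrix(contrast_maps)
  means <- colMeans(M[cluster_voxels, , drop = FALSE])
  list(roi_means = means, correlation = spearman_rho(means, delta_rmse))
}
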