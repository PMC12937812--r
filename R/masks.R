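#' Resample a region to a coarser grid as occupancy fractions
#'
#' The source grid must be an integer refinement of the target grid along
#' every axis; the occupancy of a target voxel is the fraction of its source
#' sub-voxels inside the region.
#'
#' @param source logical 3D array on the (finer) source grid.
#' @param target_shape integer vector of 3 target dimensions.
#' @return numeric 3D array of occupancy fractions in `[0, 1]`.
#' @export
region_occupancy <- function(source, target_shape) {
  sd <- dim(source)
  stopifnot(length(sd) == 3, length(target_shape) == 3)
  f <- sd / target_shape
  if (any(f != round(f)) || any(f < 1))
    stop("source grid must be an integer refinement of the target grid")
  a <- array(as.numeric(source),
             dim = c(f[1], target_shape[1], f[2], target_shape[2], f[3], target_shape[3]))
  apply(a, c(2, 4, 6), mean)
}

#' Build the brain / visual-exclusion / analysis mask set
#'
#' The visual-exclusion region (emulating a union of primary visual areas
#' defined on a finer anatomical grid) is resampled onto the functional grid,
#' retaining any voxel whose occupancy is at least
#' `overlap_fraction_threshold` (default 20\%). The analysis mask is the brain
#' mask with the resampled exclusion removed; an empty analysis mask is an
#' error because the classifier would be untrainable.
#'
#' @param grid_shape functional grid dimensions, e.g. `c(16, 16, 10)`.
#' @param brain_region_spec logical array: either on `grid_shape` or on an
#'   integer refinement (then resampled with a 50\% occupancy rule). `NULL`
#'   uses the default ellipsoidal brain.
#' @param visual_region_spec logical array for the exclusion region, on
#'   `grid_shape` or a refinement. `NULL` uses the default posterior region.
#' @param overlap_fraction_threshold minimum occupancy for a voxel to be
#'   retained in the exclusion mask.
#' @return object of class `mask_set`: list of logical arrays `brain_mask`,
#'   `visual_exclusion_mask`, `analysis_mask`, plus `grid_shape`.
#' @export
make_masks <- function(grid_shape = c(16, 16, 10),
                       brain_region_spec = NULL,
                       visual_region_spec = NULL,
                       overlap_fraction_threshold = 0.20) {
  grid_shape <- as.integer(grid_shape)
  brain_region_spec <- brain_region_spec %||% default_brain_region(grid_shape)
  visual_region_spec <- visual_region_spec %||% default_visual_region(grid_shape)
  to_mask <- function(spec, thr) {
    if (identical(dim(spec), grid_shape)) return(spec > 0)
    region_occupancy(spec, grid_shape) >= thr - 1e-12
  }
  brain <- to_mask(brain_region_spec, 0.5)
  visual <- to_mask(visual_region_spec, overlap_fraction_threshold)
  analysis <- brain & !visual
  if (!any(analysis)) stop("empty analysis mask: classifier would be untrainable")
  structure(list(brain_mask = brain, visual_exclusion_mask = visual,
                 analysis_mask = analysis, grid_shape = grid_shape),
            class = "mask_set")
}

# Ellipsoid roughly filling the grid, standing in for an automasked brain.
default_brain_region <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  rad <- pmax(grid_shape / 2 - 0.5, 1)
  idx <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                     z = seq_len(grid_shape[3]))
  inside <- ((idx$x - ctr[1]) / rad[1])^2 + ((idx$y - ctr[2]) / rad[2])^2 +
    ((idx$z - ctr[3]) / rad[3])^2 <= 1
  array(inside, dim = grid_shape)
}

# Posterior slab with graded edges, defined on a 2x finer grid so that the
# occupancy threshold rule is actually exercised.
default_visual_region <- function(grid_shape) {
  fine <- grid_shape * 2L
  ctr <- c(fine[1] / 2 + 0.5, fine[2] * 0.92, fine[3] / 2 + 0.5)
  rad <- c(fine[1] * 0.28, fine[2] * 0.14, fine[3] * 0.30)
  idx <- expand.grid(x = seq_len(fine[1]), y = seq_len(fine[2]), z = seq_len(fine[3]))
  inside <- ((idx$x - ctr[1]) / rad[1])^2 + ((idx$y - ctr[2]) / rad[2])^2 +
    ((idx$z - ctr[3]) / rad[3])^2 <= 1
  array(inside, dim = fine)
}

#' Default planted motor-network voxels
#'
#' Three compact blobs standing in for primary motor cortex, the supplementary
#' motor area and cerebellum, restricted to the analysis mask. Together they
#' cover roughly a tenth of the analysis mask.
#'
#' @param masks a `mask_set`.
#' @return integer vector of linear voxel indices.
#' @export
default_motor_voxels <- function(masks) {
  g <- masks$grid_shape
  blob <- function(xr, yr, zr) {
    idx <- expand.grid(x = xr, y = yr, z = zr)
    idx$x + (idx$y - 1) * g[1] + (idx$z - 1) * g[1] * g[2]
  }
  m1 <- blob(3:6, 4:7, 4:7)
  sma <- blob(8:10, 7:9, 7:9)
  cereb <- blob(10:12, 10:12, 2:4)
  vox <- unique(c(m1, sma, cereb))
  vox[masks$analysis_mask[vox]]
}
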