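#' Simulation ground truth for one synthetic subject
#'
#' Holds everything the generator plants into the BOLD data: the motor-network
#' voxel set, per-condition activation amplitudes (in intensity units; the
#' contrast-to-noise ratio is amplitude / `noise_sd`), per-voxel linear drift
#' slopes, per-run motion nuisance series with a small spatial coupling, and
#' the white-noise SD. Recovery tests compare estimates against these values.
#'
#' @param masks a `mask_set`.
#' @param n_runs number of runs to draw motion series for.
#' @param n_tr volumes per run.
#' @param tr_s repetition time (s).
#' @param amplitudes named per-condition activation amplitudes added to motor
#'   voxels; conditions absent from the vector contribute nothing.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param baseline baseline intensity.
#' @param drift_sd SD of per-voxel drift slope, intensity units per second.
#' @param motion_step_sd SD of the motion random-walk increments.
#' @param motion_coupling_sd SD of per-voxel motion loadings.
#' @param ar1 lag-1 autocorrelation of the noise (default 0, white noise).
#' @param motor_voxels linear indices of planted voxels; default
#'   [default_motor_voxels()].
#' @param seed integer seed.
#' @return object of class `ground_truth`.
#' @export
make_ground_truth <- function(masks, n_runs = 6, n_tr = 210, tr_s = 2,
                              amplitudes = c(tap1Hz = 1, tap4Hz = 1,
                                             ITAP = 0.6, practiceITAP = 0.6),
                              noise_sd = 1, baseline = 100,
                              drift_sd = 0.005, motion_step_sd = 0.02,
                              motion_coupling_sd = 0.1, ar1 = 0,
                              motor_voxels = NULL, seed = NULL) {
  stopifnot(noise_sd >= 0)
  motor_voxels <- motor_voxels %||% default_motor_voxels(masks)
  nv <- prod(masks$grid_shape)
  if (!all(masks$analysis_mask[motor_voxels]))
    stop("motor voxels must lie inside the analysis mask")
  with_seed(seed, {
    truth <- list(
      grid_shape = masks$grid_shape, tr_s = tr_s,
      motor_voxels = motor_voxels,
      amplitudes = amplitudes, noise_sd = noise_sd, baseline = baseline,
      drift_slope = stats::rnorm(nv, 0, drift_sd),
      motion_params = lapply(seq_len(n_runs), function(r)
        apply(matrix(stats::rnorm(n_tr * 6, 0, motion_step_sd), n_tr, 6), 2, cumsum)),
      motion_coupling = matrix(stats::rnorm(nv * 6, 0, motion_coupling_sd), nv, 6),
      ar1 = ar1)
    class(truth) <- "ground_truth"
    truth
  })
}

#' Generate one run of synthetic BOLD data
#'
#' Every voxel time course is baseline + planted signal (condition boxcar
#' convolved with the canonical HRF, scaled by the condition amplitude, in
#' motor voxels only) + linear drift + motion-coupled nuisance + Gaussian
#' noise. The result is deterministic given the seed.
#'
#' @param schedule a `block_schedule`.
#' @param masks a `mask_set` on the same grid as `truth`.
#' @param truth a `ground_truth`.
#' @param seed integer seed for the noise draw.
#' @param run_index which run this is (selects the motion series).
#' @return object of class `volume_series`: list with `data` (voxels x time
#'   matrix), `grid_shape`, `tr_s`, `run_index`.
#' @export
generate_bold_run <- function(schedule, masks, truth, seed = NULL, run_index = 1L) {
  if (abs(schedule$tr_s - truth$tr_s) > 1e-9)
    stop("TR mismatch between schedule and ground truth")
  if (!identical(as.integer(truth$grid_shape), as.integer(masks$grid_shape)))
    stop("grid mismatch between masks and ground truth")
  nt <- n_volumes(schedule)
  nv <- prod(masks$grid_shape)
  cond <- tr_conditions(schedule)
  hrf <- canonical_hrf(schedule$tr_s)
  task <- numeric(nt)
  for (cc in names(truth$amplitudes)) {
    a <- truth$amplitudes[[cc]]
    if (a == 0) next
    task <- task + a * convolve_hrf(as.numeric(!is.na(cond) & cond == cc), hrf)
  }
  times <- (seq_len(nt) - 1) * schedule$tr_s
  motion <- truth$motion_params[[min(run_index, length(truth$motion_params))]]
  if (nrow(motion) < nt) stop("motion series shorter than the run")
  dat <- matrix(truth$baseline, nv, nt)
  dat <- dat + outer(truth$drift_slope, times)
  dat <- dat + truth$motion_coupling %*% t(motion[seq_len(nt), , drop = FALSE])
  dat[truth$motor_voxels, ] <- dat[truth$motor_voxels, , drop = FALSE] +
    rep(task, each = length(truth$motor_voxels))
  if (truth$noise_sd > 0) {
    dat <- dat + with_seed(seed, {
      eps <- matrix(stats::rnorm(nv * nt, 0, truth$noise_sd), nv, nt)
      if (truth$ar1 != 0) {
        for (t in 2:nt) eps[, t] <- truth$ar1 * eps[, t - 1] +
            sqrt(1 - truth$ar1^2) * eps[, t]
      }
      eps
    })
  }
  volume_series(dat, masks$grid_shape, schedule$tr_s, run_index)
}

#' @rdname generate_bold_run
#' @param data voxels x time matrix.
#' @param grid_shape 3-vector of grid dimensions.
#' @param tr_s repetition time (s).
#' @export
volume_series <- function(data, grid_shape, tr_s, run_index = 1L) {
  stopifnot(is.matrix(data), nrow(data) == prod(grid_shape), all(is.finite(data)))
  structure(list(data = data, grid_shape = as.integer(grid_shape),
                 tr_s = tr_s, run_index = as.integer(run_index)),
            class = "volume_series")
}
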