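# Cache of blur operators keyed by grid + FWHM (building the Kronecker
# operator dominates otherwise when many runs share one grid).
.blur_cache <- new.env(parent = emptyenv())

# 1D truncated-Gaussian convolution matrix with edge renormalization.
blur_matrix_1d <- function(n, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  r <- max(1L, ceiling(3 * sigma))
  K <- outer(seq_len(n), seq_len(n), function(i, j)
    ifelse(abs(i - j) <= r, exp(-(i - j)^2 / (2 * sigma^2)), 0))
  K / rowSums(K)
}

#' Spatial Gaussian smoothing operator
#'
#' Separable Gaussian blur at a given FWHM (in voxels), expressed as a dense
#' voxels-by-voxels matrix so whole runs can be smoothed with one matrix
#' product. Kernels are truncated at 3 SD and renormalized at the edges.
#'
#' @param grid_shape 3-vector of grid dimensions.
#' @param fwhm_voxels full width at half maximum in voxels (0 disables).
#' @return a `prod(grid_shape)` square matrix (or `NULL` when `fwhm == 0`).
#' @export
blur_operator <- function(grid_shape, fwhm_voxels) {
  if (fwhm_voxels <= 0) return(NULL)
  key <- paste(c(grid_shape, fwhm_voxels), collapse = "x")
  if (!is.null(.blur_cache[[key]])) return(.blur_cache[[key]])
  Kx <- blur_matrix_1d(grid_shape[1], fwhm_voxels)
  Ky <- blur_matrix_1d(grid_shape[2], fwhm_voxels)
  Kz <- blur_matrix_1d(grid_shape[3], fwhm_voxels)
  B <- kronecker(Kz, kronecker(Ky, Kx))
  .blur_cache[[key]] <- B
  B
}

#' Smooth one volume (or a voxels-by-time matrix)
#' @param x numeric vector of length `prod(grid_shape)` or matrix with that
#'   many rows.
#' @inheritParams blur_operator
#' @export
gaussian_blur <- function(x, grid_shape, fwhm_voxels) {
  B <- blur_operator(grid_shape, fwhm_voxels)
  if (is.null(B)) return(x)
  B %*% x
}

nuisance_design <- function(n_tr, motion) {
  X <- cbind(intercept = 1, trend = seq_len(n_tr) - (n_tr + 1) / 2)
  if (!is.null(motion)) {
    stopifnot(nrow(motion) == n_tr)
    X <- cbind(X, motion)
  }
  X
}

#' Offline preprocessing of a full run
#'
#' Per voxel, the intercept (baseline), linear trend and the six motion
#' series are regressed out over the whole run; the residual series is then
#' spatially blurred. Slice-timing correction is a deliberate no-op for
#' synthetic data (generated without slice offsets); the argument order keeps
#' a hook for real data.
#'
#' @param run a `volume_series`.
#' @param motion_params n_tr x 6 matrix of known motion series (or `NULL`).
#' @param blur_fwhm_voxels spatial smoothing FWHM in voxels (default 1.5,
#'   the 6 mm-equivalent on the simulated grid).
#' @return a `volume_series` of residuals.
#' @export
offline_preprocess <- function(run, motion_params = NULL, blur_fwhm_voxels = 1.5) {
  Y <- run$data
  nt <- ncol(Y)
  X <- nuisance_design(nt, motion_params)
  q <- qr(X)
  if (q$rank < ncol(X))
    stop("singular nuisance design: columns ",
         paste(which(colSums(abs(qr.Q(q) %*% qr.R(q) - X)) > 1e-8), collapse = ","),
         " are collinear")
  # residualize all voxels at once: E = Y (I - H)
  H <- X %*% solve(crossprod(X), t(X))
  E <- Y - Y %*% H
  E <- gaussian_blur(E, run$grid_shape, blur_fwhm_voxels)
  volume_series(E, run$grid_shape, run$tr_s, run$run_index)
}

#' Incremental (online) nuisance regression of one new volume
#'
#' Mirrors the real-time contract: nuisance coefficients (intercept, linear
#' trend, motion) are estimated only on the volumes acquired before the
#' current one, then used to residualize the new volume at its own time
#' point. With a non-empty history shorter than `min_history` the volume is
#' centered on the history mean; with an empty history it is passed through
#' unchanged.
#'
#' @param new_volume numeric vector (one volume, all voxels).
#' @param history_volumes voxels x h matrix of prior volumes (h may be 0).
#' @param history_motion h x 6 matrix of motion for the history (or `NULL`).
#' @param new_motion motion parameters of the new volume (or `NULL`).
#' @param min_history minimum history length before any regression is
#'   attempted (default 4); below it the volume is centered on the history
#'   mean (or passed through when the history is empty). In the study design
#'   the imagery practice blocks play exactly this kick-start role.
#' @param trend_min_history,motion_min_history history lengths at which the
#'   linear trend and the six motion regressors enter the model (defaults 16
#'   and 40). Growing the model with the history keeps the early-run fit
#'   from being over-parameterized, which would amplify noise in the
#'   residuals.
#' @param protect_history optional h x k matrix of known task regressors
#'   over the history (HRF-convolved condition boxcars). They are included
#'   in the estimation so the intercept/trend fit does not absorb task
#'   variance (the incremental-GLM convention of real-time analysis), but
#'   only their run-mean contribution is removed from the new volume, which
#'   keeps online residuals on the same centering as [offline_preprocess()].
#' @param protect_center length-k vector: run-mean of each protected
#'   regressor.
#' @return residualized volume (numeric vector).
#' @export
online_preprocess <- function(new_volume, history_volumes, history_motion = NULL,
                              new_motion = NULL, min_history = 4,
                              trend_min_history = 16, motion_min_history = 40,
                              protect_history = NULL, protect_center = NULL) {
  h <- if (is.null(history_volumes)) 0L else ncol(history_volumes)
  if (h == 0L) return(new_volume)
  if (h < min_history) return(new_volume - rowMeans(history_volumes))
  use_trend <- h >= trend_min_history
  use_motion <- h >= motion_min_history && !is.null(history_motion)
  Xh <- cbind(intercept = rep(1, h),
              if (use_trend) seq_len(h),
              if (use_motion) history_motion)
  xnew <- c(1, if (use_trend) h + 1, if (use_motion) new_motion)
  n_nuis <- ncol(Xh)
  if (!is.null(protect_history)) {
    stopifnot(nrow(protect_history) == h,
              length(protect_center) == ncol(protect_history))
    # a task column is identifiable only once it varies beyond the nuisance
    # subspace; otherwise its coefficient is unstable and it must sit out
    nq <- qr(Xh)
    keep <- vapply(seq_len(ncol(protect_history)), function(j)
      stats::sd(qr.resid(nq, protect_history[, j])) > 0.05, logical(1))
    Xh <- cbind(Xh, protect_history[, keep, drop = FALSE])
    xnew <- c(xnew, protect_center[keep])
  }
  qx <- qr(Xh)
  beta <- qr.coef(qx, t(history_volumes))
  if (is.vector(beta)) beta <- matrix(beta, ncol = 1)
  if (anyNA(beta[seq_len(n_nuis), 1]))  # aliased nuisance: no usable fit yet
    return(new_volume - rowMeans(history_volumes))
  beta[is.na(beta)] <- 0  # aliased task columns (not yet seen) drop out
  new_volume - drop(crossprod(beta, xnew))
}

#' Replay a whole run through the online preprocessing contract
#'
#' Applies [online_preprocess()] TR by TR (each volume residualized against
#' its own past only) and then the spatial blur, reproducing what the
#' real-time pathway would have produced for every volume of the run.
#'
#' @param run a `volume_series` (raw).
#' @param motion_params n_tr x 6 motion matrix (or `NULL`).
#' @param schedule optional `block_schedule`; when given, the known task
#'   structure (HRF-convolved condition boxcars) is protected during the
#'   incremental nuisance estimation (see [online_preprocess()]).
#' @inheritParams online_preprocess
#' @inheritParams offline_preprocess
#' @return a `volume_series` of online residuals.
#' @export
online_replay <- function(run, motion_params = NULL, schedule = NULL,
                          min_history = 4, blur_fwhm_voxels = 1.5) {
  Y <- run$data
  nt <- ncol(Y)
  U <- if (!is.null(schedule)) protect_regressors(schedule)
  Uproj <- NULL
  if (!is.null(U)) {
    # centering term: the [intercept, trend] projection of each task
    # regressor over the run, so online residuals converge to the offline
    # detrending convention (which removes exactly that projection)
    P <- cbind(1, seq_len(nt))
    Uproj <- P %*% solve(crossprod(P), crossprod(P, U))
  }
  E <- matrix(0, nrow(Y), nt)
  for (t in seq_len(nt)) {
    hist_idx <- seq_len(t - 1L)
    E[, t] <- online_preprocess(
      Y[, t],
      if (t > 1) Y[, hist_idx, drop = FALSE] else NULL,
      if (!is.null(motion_params) && t > 1) motion_params[hist_idx, , drop = FALSE],
      if (!is.null(motion_params)) motion_params[t, ],
      min_history = min_history,
      protect_history = if (!is.null(U) && t > 1) U[hist_idx, , drop = FALSE],
      protect_center = if (!is.null(U)) Uproj[t, ])
  }
  E <- gaussian_blur(E, run$grid_shape, blur_fwhm_voxels)
  volume_series(E, run$grid_shape, run$tr_s, run$run_index)
}

# Known task regressors of a schedule (HRF-convolved boxcars): one per
# tapping speed for tapping runs, one pooled imagery regressor (practice +
# ITAP) for imagery runs.
protect_regressors <- function(schedule) {
  cond <- tr_conditions(schedule)
  hrf <- canonical_hrf(schedule$tr_s)
  groups <- if (schedule$run_kind == "tapping")
    list(tap1Hz = "tap1Hz", tap4Hz = "tap4Hz")
  else list(imagery = c("practiceITAP", "ITAP"))
  U <- vapply(groups, function(g)
    convolve_hrf(as.numeric(!is.na(cond) & cond %in% g), hrf),
    numeric(length(cond)))
  matrix(U, ncol = length(groups), dimnames = list(NULL, names(groups)))
}
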