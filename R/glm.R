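#' Build a first-level GLM design matrix
#'
#' Block regressors are condition boxcars convolved with the canonical HRF;
#' event regressors are one-TR stick functions convolved with the same
#' kernel. An intercept and polynomial drift columns are appended. The design
#' is rejected if rank-deficient, naming the offending columns.
#'
#' @param n_tr number of volumes.
#' @param tr_s repetition time (s).
#' @param schedule optional `block_schedule`; each condition in `conditions`
#'   becomes one boxcar regressor.
#' @param conditions which schedule conditions get a regressor (default all
#'   non-rest conditions present).
#' @param events optional named list of TR-index vectors; each entry becomes
#'   one event regressor.
#' @param drift_order polynomial drift order (default 1, linear).
#' @param hrf HRF kernel sampled at the TR (default [canonical_hrf()]).
#' @return numeric matrix with named columns, `n_tr` rows, plus attribute
#'   `"task_columns"` naming the task regressors.
#' @export
build_design <- function(n_tr, tr_s, schedule = NULL, conditions = NULL,
                         events = NULL, drift_order = 1, hrf = NULL) {
  hrf <- hrf %||% canonical_hrf(tr_s)
  cols <- list()
  if (!is.null(schedule)) {
    cond <- tr_conditions(schedule)
    conditions <- conditions %||% setdiff(unique(cond[!is.na(cond)]), "rest")
    for (cc in conditions)
      cols[[cc]] <- convolve_hrf(as.numeric(!is.na(cond) & cond == cc), hrf)
  }
  if (!is.null(events)) {
    for (nm in names(events)) {
      u <- numeric(n_tr)
      idx <- events[[nm]]
      if (length(idx)) {
        stopifnot(all(idx >= 1 & idx <= n_tr))
        u[idx] <- 1
      }
      cols[[nm]] <- convolve_hrf(u, hrf)
    }
  }
  if (!length(cols)) stop("design has no task regressors")
  X <- do.call(cbind, cols)
  task_names <- colnames(X)
  X <- cbind(X, intercept = 1)
  if (drift_order >= 1) {
    P <- stats::poly(seq_len(n_tr), degree = drift_order)
    colnames(P) <- paste0("drift", seq_len(drift_order))
    X <- cbind(X, P)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qrx$pivot[seq_len(qrx$rank)]])
    stop("rank-deficient design; offending column(s): ", paste(bad, collapse = ", "))
  }
  attr(X, "task_columns") <- task_names
  X
}

#' Fit a first-level GLM and form one contrast per voxel
#'
#' Ordinary least squares at every voxel; the contrast estimate is
#' `c' beta_hat`. The contrast vector may be named over a subset of design
#' columns (unnamed columns weight 0) or given in full.
#'
#' @param run a `volume_series` (typically preprocessed/smoothed).
#' @param design matrix from [build_design()] with rows matching the run.
#' @param contrast named numeric vector over design columns, or full-length
#'   numeric vector.
#' @return object of class `contrast_map`: list with `estimate` (per-voxel
#'   contrast), `betas` (coefficients x voxels), `contrast`, `grid_shape`.
#' @export
fit_first_level <- function(run, design, contrast) {
  Y <- run$data
  if (ncol(Y) != nrow(design)) stop("design rows must equal run volumes")
  XtX <- crossprod(design)
  B <- tryCatch(solve(XtX, crossprod(design, t(Y))),
                error = function(e) stop("singular design"))
  cv <- numeric(ncol(design))
  names(cv) <- colnames(design)
  if (!is.null(names(contrast))) {
    if (!all(names(contrast) %in% colnames(design)))
      stop("contrast names not in design")
    cv[names(contrast)] <- contrast
  } else {
    stopifnot(length(contrast) == ncol(design))
    cv <- contrast
  }
  structure(list(estimate = drop(crossprod(B, cv)), betas = B, contrast = cv,
                 grid_shape = run$grid_shape),
            class = "contrast_map")
}

maps_matrix <- function(contrast_maps) {
  if (is.matrix(contrast_maps)) return(contrast_maps)
  est <- lapply(contrast_maps, function(m)
    if (inherits(m, "contrast_map")) m$estimate else m)
  do.call(cbind, est)  # voxels x subjects
}

#' Group one-sample t map
#'
#' Voxelwise one-sample t of per-subject contrast estimates against zero
#' (random-effects analysis), df = n - 1. Voxels with zero between-subject
#' variance get `NA` rather than an infinite statistic.
#'
#' @param contrast_maps list of `contrast_map`s (or voxels x subjects
#'   matrix), all on one grid.
#' @param grid_shape grid dimensions (taken from the maps when they are
#'   `contrast_map`s).
#' @return object of class `stat_map`: `t` (per-voxel), `df`, `model`,
#'   `grid_shape`.
#' @export
group_one_sample <- function(contrast_maps, grid_shape = NULL) {
  M <- maps_matrix(contrast_maps)
  n <- ncol(M)
  if (n < 3) stop("need at least 3 maps")
  mu <- rowMeans(M)
  sdv <- sqrt(rowSums((M - mu)^2) / (n - 1))
  tval <- ifelse(sdv > 0, mu / (sdv / sqrt(n)), NA_real_)
  gs <- grid_shape %||% (if (is.list(contrast_maps)) contrast_maps[[1]]$grid_shape)
  structure(list(t = tval, df = n - 1, model = "one-sample", grid_shape = gs),
            class = "stat_map")
}

#' Group covariate t map (improvement scores controlling for severity)
#'
#' Per voxel, the subject contrast is regressed on an intercept, the
#' improvement covariate and a control covariate; the reported statistic is
#' the improvement coefficient's t with df = n - 3.
#'
#' @inheritParams group_one_sample
#' @param delta_rmse per-subject improvement scores.
#' @param control_covariate per-subject control values (e.g. clinical
#'   severity).
#' @return a `stat_map` (model `"covariate"`), with the per-voxel slope in
#'   `$beta`.
#' @export
group_covariate <- function(contrast_maps, delta_rmse, control_covariate,
                            grid_shape = NULL) {
  M <- maps_matrix(contrast_maps)
  n <- ncol(M)
  stopifnot(length(delta_rmse) == n, length(control_covariate) == n)
  if (stats::sd(control_covariate) == 0) {
    # a constant control carries no information beyond the intercept:
    # reduce to the two-column fit
    X <- cbind(1, delta_rmse)
  } else {
    X <- cbind(1, delta_rmse, control_covariate)
    if (qr(X)$rank < 3) stop("collinear covariates")
  }
  XtX_inv <- solve(crossprod(X))
  B <- XtX_inv %*% crossprod(X, t(M))
  res <- t(M) - X %*% B
  df <- n - ncol(X)
  if (df > 0) {
    se <- sqrt(colSums(res^2) / df * XtX_inv[2, 2])
    tval <- ifelse(se > 0, B[2, ] / se, NA_real_)
  } else {
    tval <- rep(NA_real_, ncol(M))  # no residual df: t undefined everywhere
  }
  gs <- grid_shape %||% (if (is.list(contrast_maps)) contrast_maps[[1]]$grid_shape)
  structure(list(t = tval, df = df, model = "covariate", beta = B[2, ],
                 grid_shape = gs),
            class = "stat_map")
}
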