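#' Per-volume training labels from a schedule
#'
#' Tapping blocks of either speed label their TRs `"tap"`, rest blocks
#' `"rest"`; unlabelled scan time is `NA`. Labels are shifted forward by
#' `label_shift_trs` volumes so a volume is labeled by the condition that was
#' on screen one hemodynamic delay earlier.
#'
#' @param schedule a tapping `block_schedule`.
#' @param label_shift_trs non-negative integer shift (default 3, i.e. 6 s at
#'   TR 2 s, matching the canonical HRF's time to half of the block-response
#'   plateau).
#' @param censor_trs additionally blank `censor_trs` volumes on each side of
#'   every label change (default 0). During training this removes
#'   hemodynamic-transition volumes, where the BOLD response sits between
#'   its block levels and the shifted label is unreliable.
#' @return character vector of `"tap"`/`"rest"`/`NA` per volume.
#' @export
training_labels <- function(schedule, label_shift_trs = 3, censor_trs = 0) {
  cond <- tr_conditions(schedule)
  lab <- ifelse(cond %in% TAP_CONDITIONS, "tap",
                ifelse(cond == "rest", "rest", NA_character_))
  if (label_shift_trs > 0)
    lab <- c(rep(NA_character_, label_shift_trs),
             lab[seq_len(length(lab) - label_shift_trs)])
  if (censor_trs > 0) {
    seg <- rle(ifelse(is.na(lab), "<na>", lab))
    ends <- cumsum(seg$lengths)
    starts <- ends - seg$lengths + 1L
    for (i in seq_along(seg$lengths)) {
      if (seg$values[i] == "<na>") next
      head_trs <- starts[i]:min(starts[i] + censor_trs - 1L, ends[i])
      tail_trs <- max(starts[i], ends[i] - censor_trs + 1L):ends[i]
      lab[c(head_trs, tail_trs)] <- NA
    }
  }
  lab
}

#' Train the tapping-vs-rest linear decision rule
#'
#' Fits a linear soft-margin SVM (via \pkg{e1071}/LIBSVM) on the preprocessed volumes of the two training runs, restricted
#' to analysis-mask voxels; visual-exclusion voxels therefore carry exactly
#' zero weight. Labels come from the schedules via [training_labels()], with
#' the first `censor_trs` volumes of every block dropped from training so
#' that hemodynamic-transition volumes (whose shifted labels conflict with
#' the mid-ramp BOLD signal) do not force the margin onto noise voxels.
#'
#' @param runs list of two preprocessed `volume_series` (runs 1-2).
#' @param schedules list of the matching `block_schedule`s.
#' @param masks a `mask_set` on the runs' grid.
#' @param label_shift_trs hemodynamic label shift in TRs.
#' @param censor_trs transition volumes censored per block during training
#'   (default 2).
#' @param cost soft-margin penalty (default 0.001). The default is heavily
#'   regularized: with wide margins the discriminant approaches the class-mean
#'   difference, which keeps the voxel weight map on the informative pattern
#'   instead of the noise components of a few support vectors.
#' @return object of class `classifier_model`: `weights` (full-grid vector,
#'   zero outside the analysis mask), `bias`, `grid_shape`, `training_meta`.
#' @export
train_classifier <- function(runs, schedules, masks, label_shift_trs = 3,
                             censor_trs = 2, cost = 0.001) {
  stopifnot(length(runs) == length(schedules))
  grid <- runs[[1]]$grid_shape
  for (r in runs) if (!identical(r$grid_shape, grid))
    stop("training runs must share one grid")
  vox <- which(masks$analysis_mask)
  X <- NULL; y <- character(0)
  for (i in seq_along(runs)) {
    lab <- training_labels(schedules[[i]], label_shift_trs, censor_trs)
    keep <- !is.na(lab)
    X <- rbind(X, t(runs[[i]]$data[vox, keep, drop = FALSE]))
    y <- c(y, lab[keep])
  }
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  y <- factor(y, levels = c("tap", "rest"))
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision value toward the class seen first in the
  # data; enforce "positive = tap" explicitly
  dv <- drop(X %*% w) + b
  if (mean(dv[y == "tap"]) < mean(dv[y == "rest"])) {
    w <- -w
    b <- -b
  }
  weights <- numeric(prod(grid))
  weights[vox] <- w
  structure(list(weights = weights, bias = b, grid_shape = grid,
                 analysis_voxels = vox,
                 training_meta = list(label_shift_trs = label_shift_trs,
                                      censor_trs = censor_trs,
                                      cost = cost, n_train = length(y))),
            class = "classifier_model")
}

#' Decode one volume
#'
#' The decision value is the signed distance-to-hyperplane surrogate
#' `w . x + b` over analysis-mask voxels; the label is `"tap"` iff the value
#' is strictly positive (a value of exactly 0 decodes as `"rest"`).
#'
#' @param model a `classifier_model`.
#' @param volume numeric vector on the model grid.
#' @param tr_index optional volume index carried into the result.
#' @return list with `tr_index`, `decision_value`, `label`.
#' @export
decode <- function(model, volume, tr_index = NA_integer_) {
  if (length(volume) != length(model$weights))
    stop("volume is not on the model grid")
  dv <- sum(model$weights * volume) + model$bias
  list(tr_index = tr_index, decision_value = dv,
       label = if (dv > 0) "tap" else "rest")
}

#' Decode every volume of a processed run
#' @param model a `classifier_model`.
#' @param run a preprocessed `volume_series`.
#' @return data.frame with `tr_index`, `decision_value`, `label`.
#' @export
decode_series <- function(model, run) {
  if (nrow(run$data) != length(model$weights))
    stop("run is not on the model grid")
  dv <- drop(crossprod(run$data, model$weights)) + model$bias
  data.frame(tr_index = seq_len(ncol(run$data)), decision_value = dv,
             label = ifelse(dv > 0, "tap", "rest"))
}

#' Held-out classifier accuracy on the post-neurofeedback tapping runs
#'
#' Replays the held-out runs through the online preprocessing contract,
#' decodes every labeled volume and reports per-class and overall accuracy,
#' the positive control of the study design.
#'
#' @param model a `classifier_model`.
#' @param runs list of raw `volume_series` (runs 5-6).
#' @param schedules matching schedules.
#' @param motion_params list of motion matrices (or `NULL`s).
#' @param label_shift_trs label shift used for scoring (defaults to the
#'   model's training shift).
#' @param warmup_trs leading volumes excluded from scoring (default 32, one
#'   full rest + tapping cycle at the longest block length). Until the
#'   online history contains both conditions, the baseline and the task
#'   level are not separately identifiable, so decodes during the first
#'   cycle reflect the cold start rather than the classifier; the imagery
#'   runs avoid this by design through their practice blocks.
#' @param min_history,blur_fwhm_voxels online preprocessing settings.
#' @return list with `tap_acc`, `rest_acc`, `overall_acc`, `n_scored`.
#' @export
evaluate_held_out <- function(model, runs, schedules, motion_params = NULL,
                              label_shift_trs = NULL, warmup_trs = 32,
                              min_history = 4, blur_fwhm_voxels = 1.5) {
  label_shift_trs <- label_shift_trs %||% model$training_meta$label_shift_trs
  pred <- character(0); truth <- character(0)
  for (i in seq_along(runs)) {
    proc <- online_replay(runs[[i]], motion_params[[i]],
                          schedule = schedules[[i]],
                          min_history = min_history,
                          blur_fwhm_voxels = blur_fwhm_voxels)
    dec <- decode_series(model, proc)
    lab <- training_labels(schedules[[i]], label_shift_trs)
    keep <- !is.na(lab) & dec$tr_index > warmup_trs
    pred <- c(pred, dec$label[keep])
    truth <- c(truth, lab[keep])
  }
  list(tap_acc = mean(pred[truth == "tap"] == "tap"),
       rest_acc = mean(pred[truth == "rest"] == "rest"),
       overall_acc = mean(pred == truth),
       n_scored = length(truth))
}
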