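#' Study configuration
#'
#' Bundles every tunable of the simulated study with the defaults that
#' mirror the experimental design: 16 subjects, a 16 x 16 x 10 voxel grid
#' with 210 volumes per run at TR 2 s, six runs per subject in the order
#' tapping, tapping, imagery, imagery, tapping, tapping, a 2-TR
#' (4 s) decode-to-display latency, a 3-TR hemodynamic label shift, and
#' p < 0.001 with minimum cluster extents of 17 (tapping), 16 (imagery) and
#' 15 (covariate) voxels.
#'
#' @param n_subjects cohort size.
#' @param grid_shape voxel grid.
#' @param tr_s repetition time (s).
#' @param total_duration_s run duration (s).
#' @param cnr tapping contrast-to-noise ratio.
#' @param imagery_gain imagery amplitude relative to tapping.
#' @param coupling_strength planted correlation between imagery amplitude
#'   and tapping improvement.
#' @param latency_trs feedback latency (TRs).
#' @param label_shift_trs training label shift (TRs).
#' @param blur_fwhm_voxels classifier-path smoothing FWHM (voxels; 6 mm
#'   equivalent).
#' @param glm_fwhm_voxels first-level analysis smoothing FWHM (voxels; 8 mm
#'   equivalent).
#' @param p_voxel voxelwise threshold.
#' @param k_tapping,k_imagery,k_covariate minimum cluster extents.
#' @param covariate_speed which improvement score feeds the covariate
#'   analysis: `"1"` or `"4"` (Hz), or `"mean"` (default), the average of
#'   the 1 Hz score and half the 4 Hz score — both speeds index the same
#'   underlying ability (the 4 Hz score on twice the scale), so averaging
#'   them reduces measurement noise.
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_subjects = 16, grid_shape = c(16, 16, 10),
                         tr_s = 2, total_duration_s = 420, cnr = 1,
                         imagery_gain = 0.6, coupling_strength = 0.8,
                         latency_trs = 2, label_shift_trs = 3,
                         blur_fwhm_voxels = 1.5, glm_fwhm_voxels = 2,
                         p_voxel = 0.001, k_tapping = 17, k_imagery = 16,
                         k_covariate = 15, covariate_speed = "mean",
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_subjects >= 3, abs(cfg$coupling_strength) <= 1)
  class(cfg) <- "study_config"
  cfg
}

first_level_tapping <- function(session, cfg) {
  maps <- list()
  for (r in c(1, 2, 5, 6)) {
    run <- session$runs[[r]]$volumes
    sched <- session$runs[[r]]$schedule
    run_s <- volume_series(gaussian_blur(run$data, run$grid_shape, cfg$glm_fwhm_voxels),
                           run$grid_shape, run$tr_s, r)
    X <- build_design(n_volumes(sched), cfg$tr_s, schedule = sched,
                      conditions = c("tap1Hz", "tap4Hz"))
    maps[[length(maps) + 1]] <-
      fit_first_level(run_s, X, c(tap1Hz = 0.5, tap4Hz = 0.5))
  }
  est <- rowMeans(do.call(cbind, lapply(maps, `[[`, "estimate")))
  structure(list(estimate = est, grid_shape = session$masks$grid_shape),
            class = "contrast_map")
}

first_level_imagery <- function(session, traces, cfg) {
  maps <- list()
  for (i in seq_along(traces)) {
    r <- c(3, 4)[i]
    run <- session$runs[[r]]$volumes
    sched <- session$runs[[r]]$schedule
    tr <- traces[[i]]
    ev <- list(true_itap = tr$tr_index[tr$outcome == "TP"],
               other_imagery = tr$tr_index[tr$outcome %in% c("FP", "TN", "FN")])
    run_s <- volume_series(gaussian_blur(run$data, run$grid_shape, cfg$glm_fwhm_voxels),
                           run$grid_shape, run$tr_s, r)
    X <- build_design(n_volumes(sched), cfg$tr_s, events = ev)
    maps[[i]] <- fit_first_level(run_s, X, c(true_itap = 1, other_imagery = -1))
  }
  est <- rowMeans(do.call(cbind, lapply(maps, `[[`, "estimate")))
  structure(list(estimate = est, grid_shape = session$masks$grid_shape),
            class = "contrast_map")
}

#' Replay the real-time pathway for one subject
#'
#' Imagery runs 3-4 are replayed through the feedback state machine with
#' online preprocessing; tapping runs 5-6 are decoded as the held-out
#' positive control.
#'
#' @param session a `synthetic_session` with all six runs.
#' @param model the subject's trained `classifier_model`.
#' @param config a [study_config()].
#' @return list with `traces` (feedback traces for runs 3-4), `imagery`
#'   (per-run [score_trace()] results), `held_out`
#'   ([evaluate_held_out()] result).
#' @export
replay_realtime <- function(session, model, config = study_config()) {
  if (!is.function(model) &&
      !identical(model$grid_shape, session$masks$grid_shape))
    stop("model/grid mismatch")
  traces <- lapply(1:2, function(i) {
    r <- c(3, 4)[i]
    run_feedback(model, session$runs[[r]]$volumes, session$runs[[r]]$schedule,
                 motion_params = session$truth$motion_params[[r]],
                 latency_trs = config$latency_trs,
                 min_history = 4, blur_fwhm_voxels = config$blur_fwhm_voxels)
  })
  held <- evaluate_held_out(
    model,
    runs = list(session$runs[[5]]$volumes, session$runs[[6]]$volumes),
    schedules = list(session$runs[[5]]$schedule, session$runs[[6]]$schedule),
    motion_params = session$truth$motion_params[c(5, 6)],
    label_shift_trs = config$label_shift_trs,
    blur_fwhm_voxels = config$blur_fwhm_voxels)
  list(traces = traces, imagery = lapply(traces, score_trace), held_out = held)
}

#' Run the full simulated study
#'
#' Executes the study flow end to end on a synthetic cohort: generate
#' sessions, train each subject's decoder on runs 1-2, replay the imagery
#' neurofeedback runs, evaluate the held-out tapping runs, score behavior,
#' fit first-level GLMs, and compute group maps (one-sample tapping and
#' imagery, improvement covariate controlling for clinical severity),
#' cluster tables, ROI correlation and group behavioral statistics. The
#' result is fully determined by the configuration and its master seed.
#'
#' @param config a [study_config()].
#' @return list of class `study_report`.
#' @export
run_study <- function(config = study_config()) {
  cfg <- config
  params <- cohort_parameters(cfg$n_subjects, cfg$coupling_strength,
                              seed = derive_seed(cfg$seed, "cohort_params"))
  masks <- make_masks(cfg$grid_shape)
  tap_maps <- list(); imagery_maps <- list()
  tap_scores <- list(); improvements <- list()
  imagery_acc <- list(); held_out <- list()
  for (i in seq_len(cfg$n_subjects)) {
    session <- tryCatch(
      generate_session(derive_seed(cfg$seed, paste0("subject", i)),
                       subject = params[i, ], masks = masks,
                       grid_shape = cfg$grid_shape, tr_s = cfg$tr_s,
                       total_duration_s = cfg$total_duration_s, cnr = cfg$cnr,
                       imagery_gain = cfg$imagery_gain),
      error = function(e) stop_stage("generate", conditionMessage(e)))
    model <- tryCatch({
      pre <- lapply(1:2, function(r)
        offline_preprocess(session$runs[[r]]$volumes,
                           session$truth$motion_params[[r]],
                           blur_fwhm_voxels = cfg$blur_fwhm_voxels))
      train_classifier(pre, lapply(session$runs[1:2], `[[`, "schedule"),
                       masks, label_shift_trs = cfg$label_shift_trs)
    }, error = function(e) stop_stage("train", conditionMessage(e)))
    rt <- tryCatch(replay_realtime(session, model, cfg),
                   error = function(e) stop_stage("replay", conditionMessage(e)))
    sc <- tryCatch(session_tap_scores(session),
                   error = function(e) stop_stage("score", conditionMessage(e)))
    sc$subject_id <- i
    imp <- session_improvement(session)
    imp$subject_id <- i
    tap_scores[[i]] <- sc
    improvements[[i]] <- imp
    imagery_acc[[i]] <- data.frame(
      subject_id = i, run = c(3, 4),
      itap_acc = vapply(rt$imagery, function(s) s$accuracy$itap_acc, numeric(1)),
      noitap_acc = vapply(rt$imagery, function(s) s$accuracy$noitap_acc, numeric(1)),
      overall_acc = vapply(rt$imagery, function(s) s$accuracy$overall_acc, numeric(1)))
    held_out[[i]] <- data.frame(subject_id = i,
                                tap_acc = rt$held_out$tap_acc,
                                rest_acc = rt$held_out$rest_acc,
                                overall_acc = rt$held_out$overall_acc)
    tap_maps[[i]] <- tryCatch(first_level_tapping(session, cfg),
                              error = function(e) stop_stage("glm", conditionMessage(e)))
    imagery_maps[[i]] <- tryCatch(first_level_imagery(session, rt$traces, cfg),
                                  error = function(e) stop_stage("glm", conditionMessage(e)))
  }
  tap_scores <- do.call(rbind, tap_scores)
  improvements <- do.call(rbind, improvements)
  imagery_acc <- do.call(rbind, imagery_acc)
  held_out <- do.call(rbind, held_out)
  delta <- improvement_covariate(improvements, cfg$covariate_speed)

  group <- tryCatch({
    tap_map <- group_one_sample(tap_maps)
    img_map <- group_one_sample(imagery_maps)
    cov_map <- group_covariate(imagery_maps, delta, params$icars)
    list(
      tapping = list(map = tap_map,
                     clusters = cluster_threshold(tap_map, cfg$p_voxel, cfg$k_tapping)),
      imagery = list(map = img_map,
                     clusters = cluster_threshold(img_map, cfg$p_voxel, cfg$k_imagery)),
      covariate = list(map = cov_map,
                       clusters = cluster_threshold(cov_map, cfg$p_voxel, cfg$k_covariate)))
  }, error = function(e) stop_stage("group", conditionMessage(e)))
  roi <- NULL
  if (nrow(group$covariate$clusters) > 0) {
    vox <- which(attr(group$covariate$clusters, "labels") ==
                   group$covariate$clusters$cluster_id[1])
    roi <- roi_summary(imagery_maps, vox, delta)
  }
  # group behavioral statistics
  rmse_cells <- array(NA_real_, c(cfg$n_subjects, 4, 2))
  for (ri in seq_along(c(1, 2, 5, 6))) for (si in 1:2) {
    r <- c(1, 2, 5, 6)[ri]; speed <- c(1, 4)[si]
    v <- tap_scores$rmse_hz[tap_scores$run_index == r & tap_scores$rate_hz == speed]
    rmse_cells[, ri, si] <- v
  }
  stats_out <- list(
    rmse_anova = rm_anova(rmse_cells, factor_names = c("run", "speed")),
    wilcoxon_run2_vs_5 = lapply(stats::setNames(c(1, 4), c("1Hz", "4Hz")), function(sp) {
      r2 <- tap_scores$rmse_hz[tap_scores$run_index == 2 & tap_scores$rate_hz == sp]
      r5 <- tap_scores$rmse_hz[tap_scores$run_index == 5 & tap_scores$rate_hz == sp]
      wilcoxon_signed_rank(r2, r5)
    }),
    imagery_vs_chance = lapply(stats::setNames(c(3, 4), c("run3", "run4")), function(r)
      one_sample_t(100 * imagery_acc$overall_acc[imagery_acc$run == r], mu = 50)),
    held_out_vs_chance = one_sample_t(100 * held_out$overall_acc, mu = 50),
    roi_spearman = if (!is.null(roi)) roi$correlation)
  structure(list(config = cfg, parameters = params,
                 tap_scores = tap_scores, improvements = improvements,
                 imagery_accuracy = imagery_acc, held_out = held_out,
                 group = group, roi = roi, stats = stats_out,
                 imagery_contrasts = maps_matrix(imagery_maps),
                 covariate = list(delta_rmse = delta, control = params$icars),
                 provenance = list(seed = cfg$seed,
                                   config_hash = config_hash(cfg))),
            class = "study_report")
}

#' Per-subject improvement covariate
#'
#' @param improvements stacked [session_improvement()] rows with
#'   `subject_id`.
#' @param speed `"1"`, `"4"` or `"mean"` (average of the 1 Hz score and half
#'   the 4 Hz score).
#' @return numeric vector, one value per subject in `subject_id` order.
#' @export
improvement_covariate <- function(improvements, speed = "mean") {
  sid <- sort(unique(improvements$subject_id))
  d1 <- improvements$delta_rmse_hz[improvements$rate_hz == 1][match(sid, improvements$subject_id[improvements$rate_hz == 1])]
  d4 <- improvements$delta_rmse_hz[improvements$rate_hz == 4][match(sid, improvements$subject_id[improvements$rate_hz == 4])]
  switch(as.character(speed),
         "1" = d1,
         "4" = d4,
         "mean" = (d1 + 0.5 * d4) / 2,
         stop("covariate_speed must be '1', '4' or 'mean'"))
}

# Order-stable hash of the configuration (provenance; changes iff the
# configuration or seed changes).
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}
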