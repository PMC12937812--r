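#' Draw per-subject cohort parameters
#'
#' The cohort couples imagery ability to tapping improvement: the subject's
#' imagery activation amplitude is lognormal (mean 1, always positive,
#' mirroring the large heterogeneity of imagery performance across
#' subjects), and the improvement latent is
#' `z_delta = coupling * std(amp) + sqrt(1 - coupling^2) * z_ind`, so the
#' population correlation between the imagery amplitude itself and the
#' improvement equals `coupling_strength` exactly. An independent
#' clinical-severity nuisance covariate (ICARS-like, 0-100 scale) is drawn
#' per subject.
#'
#' @param n_subjects cohort size (>= 3).
#' @param coupling_strength population correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @param amp_sdlog log-scale SD of the imagery amplitude factor
#'   (default 0.5, i.e. a coefficient of variation of about 0.53).
#' @param delta_mean_hz,delta_sd_hz mean and SD of the planted 1 Hz
#'   improvement (Hz); the 4 Hz improvement uses twice the SD.
#' @return data.frame with one row per subject: `subject_id`, `z_amp`,
#'   `amp_factor`, `delta1_hz`, `delta4_hz`, `icars`.
#' @export
cohort_parameters <- function(n_subjects, coupling_strength, seed = NULL,
                              amp_sdlog = 0.5, delta_mean_hz = 0.001,
                              delta_sd_hz = 0.010) {
  if (n_subjects < 3) stop("need at least 3 subjects")
  if (abs(coupling_strength) > 1) stop("|coupling_strength| must be <= 1")
  with_seed(seed, {
    z_amp <- stats::rnorm(n_subjects)
    z_ind <- stats::rnorm(n_subjects)
    amp_factor <- exp(amp_sdlog * z_amp - amp_sdlog^2 / 2)  # mean 1
    amp_std <- (amp_factor - 1) / sqrt(exp(amp_sdlog^2) - 1)
    z_delta <- coupling_strength * amp_std +
      sqrt(1 - coupling_strength^2) * z_ind
    data.frame(
      subject_id = seq_len(n_subjects),
      z_amp = z_amp,
      amp_factor = amp_factor,
      delta1_hz = delta_mean_hz + delta_sd_hz * z_delta,
      delta4_hz = delta_mean_hz + 2 * delta_sd_hz * z_delta,
      icars = pmin(100, pmax(0, stats::rnorm(n_subjects, 40, 15))))
  })
}

# Run-level RMSE targets (Hz), before the per-subject spread; rows are the
# four tapping runs in session order (1, 2, 5, 6).
.rmse_targets <- function() {
  matrix(c(0.038, 0.024, NA, 0.033,
           0.056, 0.062, NA, 0.065),
         nrow = 4, ncol = 2,
         dimnames = list(c("run1", "run2", "run5", "run6"), c("1", "4")))
}

#' Generate one complete synthetic session
#'
#' Six runs in the study order (tapping, tapping, imagery, imagery, tapping,
#' tapping) on a shared mask set, with tap streams for the four tapping runs.
#' Tap-timing jitter is set per run and speed so that the expected RMSE
#' matches the run-level targets; run 5's target is run 2's minus the
#' subject's planted improvement, which realizes the cohort coupling in the
#' measured behavior.
#'
#' @param seed integer seed; all content is derived from it.
#' @param subject one row of [cohort_parameters()], or `NULL` to draw a
#'   standalone subject (uncoupled).
#' @param masks optional shared `mask_set`.
#' @param grid_shape,tr_s,total_duration_s grid and timing of every run.
#' @param cnr contrast-to-noise ratio of overt tapping (amplitude at
#'   `noise_sd` 1).
#' @param imagery_gain imagery amplitude relative to overt tapping
#'   (default 0.6; the study does not constrain it, so it is a parameter).
#' @param miss_prob per-tap miss probability.
#' @param rmse_spread_sdlog between-subject log-scale SD applied to the
#'   RMSE targets.
#' @param which_runs `"all"` for the full session or `"imagery"` for only the
#'   imagery runs plus the tapping behavior needed for improvement scores
#'   (used by large calibration simulations).
#' @return object of class `synthetic_session`: list with `runs` (list of
#'   `list(volumes, schedule)` in session order; volumes may be `NULL` for
#'   runs skipped by `which_runs`), `tap_streams` (per tapping run, per
#'   speed), `masks`, `truth`, `subject`, `seed`.
#' @export
generate_session <- function(seed, subject = NULL, masks = NULL,
                             grid_shape = c(16, 16, 10), tr_s = 2,
                             total_duration_s = 420, cnr = 1,
                             imagery_gain = 0.6, miss_prob = 0.01,
                             rmse_spread_sdlog = 0.35,
                             which_runs = c("all", "imagery")) {
  which_runs <- match.arg(which_runs)
  if (is.null(subject))
    subject <- cohort_parameters(3, 0, seed = derive_seed(seed, "solo"))[1, ]
  masks <- masks %||% make_masks(grid_shape)
  run_kinds <- c("tapping", "tapping", "imagery", "imagery", "tapping", "tapping")
  n_tr <- as.integer(round(total_duration_s / tr_s))
  amps <- c(tap1Hz = cnr, tap4Hz = cnr,
            ITAP = cnr * imagery_gain * subject$amp_factor,
            practiceITAP = cnr * imagery_gain * subject$amp_factor)
  truth <- make_ground_truth(masks, n_runs = 6, n_tr = n_tr, tr_s = tr_s,
                             amplitudes = amps,
                             seed = derive_seed(seed, "truth"))
  runs <- vector("list", 6)
  for (r in 1:6) {
    sched <- if (run_kinds[r] == "tapping")
      make_tapping_schedule(tr_s, total_duration_s, seed = derive_seed(seed, paste0("sched", r)))
    else
      make_imagery_schedule(tr_s, total_duration_s, seed = derive_seed(seed, paste0("sched", r)))
    vols <- NULL
    if (which_runs == "all" || run_kinds[r] == "imagery")
      vols <- generate_bold_run(sched, masks, truth,
                                seed = derive_seed(seed, paste0("bold", r)),
                                run_index = r)
    runs[[r]] <- list(volumes = vols, schedule = sched)
  }
  # behavioral targets: subject-level multiplicative spread, run-5 target
  # lowered by the planted improvement
  sf <- with_seed(derive_seed(seed, "rmse_spread"),
                  exp(stats::rnorm(1, 0, rmse_spread_sdlog)))
  targ <- .rmse_targets() * sf
  targ["run5", "1"] <- max(0.004, targ["run2", "1"] - subject$delta1_hz)
  targ["run5", "4"] <- max(0.004, targ["run2", "4"] - subject$delta4_hz)
  tap_runs <- c(1, 2, 5, 6)
  tap_streams <- list()
  for (i in seq_along(tap_runs)) {
    r <- tap_runs[i]
    sched <- runs[[r]]$schedule
    per_speed <- list()
    for (speed in c(1, 4)) {
      ccond <- if (speed == 1) "tap1Hz" else "tap4Hz"
      rmse_t <- targ[i, as.character(speed)]
      sdj <- rmse_t / (speed^2 * sqrt(2))
      bl <- sched$blocks[sched$blocks$condition == ccond, , drop = FALSE]
      per_speed[[as.character(speed)]] <- lapply(seq_len(nrow(bl)), function(j)
        generate_tap_stream(speed, sdj, miss_prob, bl$onset_s[j], bl$duration_s[j],
                            seed = derive_seed(seed, paste0("tap", r, "_", speed, "_", j)),
                            block_id = bl$block_id[j]))
    }
    tap_streams[[paste0("run", r)]] <- per_speed
  }
  structure(list(runs = runs, tap_streams = tap_streams, masks = masks,
                 truth = truth, subject = subject, seed = seed),
            class = "synthetic_session")
}

#' Generate a synthetic cohort
#'
#' @inheritParams cohort_parameters
#' @param ... passed on to [generate_session()].
#' @return list of `synthetic_session`, with the parameter table attached as
#'   attribute `"parameters"`.
#' @export
generate_cohort <- function(n_subjects, coupling_strength, seed, ...) {
  params <- cohort_parameters(n_subjects, coupling_strength,
                              seed = derive_seed(seed, "cohort_params"))
  sessions <- lapply(seq_len(n_subjects), function(i)
    generate_session(derive_seed(seed, paste0("subject", i)),
                     subject = params[i, ], ...))
  attr(sessions, "parameters") <- params
  sessions
}

#' Behavioral summary of a session's tapping runs
#'
#' @param session a `synthetic_session`.
#' @return data.frame of [tap_score()] rows for runs 1, 2, 5, 6 at both
#'   speeds.
#' @export
session_tap_scores <- function(session) {
  out <- list()
  for (rn in names(session$tap_streams)) {
    r <- as.integer(sub("run", "", rn))
    for (speed in c("1", "4")) {
      out[[paste(rn, speed)]] <- tap_score(session$tap_streams[[rn]][[speed]],
                                           as.numeric(speed), run_index = r)
    }
  }
  do.call(rbind, unname(out))
}

#' Improvement scores (runs 2 vs 5) of a session
#'
#' @param session a `synthetic_session`.
#' @return data.frame with one row per speed (`rate_hz`, `delta_rmse_hz`).
#' @export
session_improvement <- function(session) {
  sc <- session_tap_scores(session)
  out <- lapply(c(1, 4), function(speed)
    improvement_score(sc[sc$run_index == 2 & sc$rate_hz == speed, ],
                      sc[sc$run_index == 5 & sc$rate_hz == speed, ]))
  do.call(rbind, out)
}
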