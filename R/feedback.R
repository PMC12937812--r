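ideal_display <- function(condition) {
  ifelse(condition %in% c("practiceITAP", "ITAP"), "flashing_2hz", "static_cross")
}

#' Replay an imagery run through the feedback state machine
#'
#' The display at TR `t` is driven by the decode of the volume acquired
#' `latency_trs` earlier (the acquisition-to-analysis latency of the
#' real-time pathway, 2 TRs = 4 s by default). Practice blocks always show
#' the ideal pattern, as do TRs whose driving volume precedes the run.
#' Outcomes are scored per non-practice imagery TR against what the display
#' did on that TR: ITAP with a flashing cross is a true positive, noITAP
#' with a static cross a true negative, and so on; practice and unlabelled
#' TRs are unscored.
#'
#' @param model a `classifier_model`, or a function `(volume, tr_index)`
#'   returning a list with `decision_value` and `label` (e.g. an oracle
#'   decoder in tests).
#' @param run raw imagery `volume_series` (preprocessed online during the
#'   replay), or an already-processed series with `preprocess = FALSE`.
#' @param schedule the imagery `block_schedule` (must start with the two
#'   practice blocks).
#' @param motion_params n_tr x 6 motion matrix (or `NULL`).
#' @param latency_trs decode-to-display latency in TRs.
#' @param preprocess run the online preprocessing contract during replay.
#' @param min_history,blur_fwhm_voxels online preprocessing settings.
#' @return object of class `feedback_trace`: data.frame with one row per TR
#'   (`tr_index`, `condition`, `decision_value`, `decoded_label`, `display`,
#'   `outcome`).
#' @export
run_feedback <- function(model, run, schedule, motion_params = NULL,
                         latency_trs = 2, preprocess = TRUE,
                         min_history = 4, blur_fwhm_voxels = 1.5) {
  if (schedule$run_kind != "imagery" ||
      !identical(schedule$blocks$condition[1:2], c("practiceITAP", "practiceNoITAP")))
    stop("feedback replay needs an imagery schedule with 2 leading practice blocks")
  proc <- if (preprocess)
    online_replay(run, motion_params, schedule = schedule,
                  min_history = min_history,
                  blur_fwhm_voxels = blur_fwhm_voxels)
  else run
  nt <- ncol(proc$data)
  cond <- tr_conditions(schedule)
  if (is.function(model)) {
    dec <- lapply(seq_len(nt), function(t) model(proc$data[, t], t))
    dvals <- vapply(dec, function(d) d$decision_value, numeric(1))
    labels <- vapply(dec, function(d) d$label, character(1))
  } else {
    ds <- decode_series(model, proc)
    dvals <- ds$decision_value
    labels <- ds$label
  }
  src <- seq_len(nt) - latency_trs
  has_decode <- src >= 1
  display <- character(nt)
  shown_dv <- rep(NA_real_, nt)
  shown_label <- rep(NA_character_, nt)
  for (t in seq_len(nt)) {
    if (is.na(cond[t])) {
      display[t] <- "static_cross"
    } else if (cond[t] %in% IMAGERY_PRACTICE || !has_decode[t]) {
      display[t] <- ideal_display(cond[t])
    } else {
      shown_dv[t] <- dvals[src[t]]
      shown_label[t] <- labels[src[t]]
      display[t] <- if (shown_label[t] == "tap") "flashing_2hz" else "static_cross"
    }
  }
  outcome <- rep("unscored", nt)
  scored <- !is.na(cond) & cond %in% IMAGERY_MAIN
  flash <- display == "flashing_2hz"
  outcome[scored & cond == "ITAP" & flash] <- "TP"
  outcome[scored & cond == "ITAP" & !flash] <- "FN"
  outcome[scored & cond == "noITAP" & flash] <- "FP"
  outcome[scored & cond == "noITAP" & !flash] <- "TN"
  trace <- data.frame(tr_index = seq_len(nt), condition = cond,
                      decision_value = shown_dv, decoded_label = shown_label,
                      display = display, outcome = outcome)
  class(trace) <- c("feedback_trace", class(trace))
  trace
}

#' Score a feedback trace
#'
#' Counts TR-wise outcomes and computes the accuracy triplet: ITAP accuracy
#' `tp / (tp + fn)`, noITAP accuracy `tn / (tn + fp)` and overall accuracy
#' `(tp + tn) / (tp + fn + tn + fp)`. A class with no scored TRs yields `NA`
#' for its accuracy.
#'
#' @param trace a `feedback_trace`.
#' @return list with `counts` (`tp`, `fp`, `tn`, `fn`, `n_scored`) and
#'   `accuracy` (`itap_acc`, `noitap_acc`, `overall_acc`, as fractions).
#' @export
score_trace <- function(trace) {
  tp <- sum(trace$outcome == "TP"); fp <- sum(trace$outcome == "FP")
  tn <- sum(trace$outcome == "TN"); fn <- sum(trace$outcome == "FN")
  n <- tp + fp + tn + fn
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(counts = list(tp = tp, fp = fp, tn = tn, fn = fn, n_scored = n),
       accuracy = list(itap_acc = safe(tp, tp + fn),
                       noitap_acc = safe(tn, tn + fp),
                       overall_acc = safe(tp + tn, n)))
}
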