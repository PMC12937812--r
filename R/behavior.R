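#' Instantaneous tapping rates
#'
#' For each new tap the time elapsed since the previous tap is converted to a
#' rate (1/interval). With fewer than two taps no rate is computable.
#'
#' @param tap_times_s strictly increasing tap times in seconds.
#' @return numeric vector of rates in Hz, length `n_taps - 1` (or empty).
#' @export
instantaneous_rates <- function(tap_times_s) {
  if (length(tap_times_s) < 2) return(numeric(0))
  d <- diff(tap_times_s)
  if (any(d <= 0)) stop("tap times must be strictly increasing")
  1 / d
}

as_stream_list <- function(streams) {
  if (inherits(streams, "tap_stream")) list(streams) else streams
}

#' Tapping RMSE against the instructed rate
#'
#' Each tap's instantaneous rate is compared with the instructed rate; the
#' per-tap errors are pooled across all same-rate blocks of a run and the
#' root mean square of the pooled errors is returned. Intervals flagged as
#' prolonged inactivity by the missed-tap rule (a gap long enough to contain
#' at least one missed tap, i.e. `round(dt * rate) - 1 >= 1`) are scored by
#' [missed_tap_fraction()] instead and excluded here, so the RMSE measures
#' timing precision while the missed-tap fraction measures inactivity; this
#' separation is what makes millihertz-scale RMSE values coexist with a
#' nonzero missed-tap percentage. When no stream yields a computable rate
#' the score is undefined and `NA` is returned (never a silent 0).
#'
#' @param streams a `tap_stream` or list of them, all at the same rate.
#' @param instructed_rate_hz the instructed rate (1 or 4 Hz in the study
#'   design).
#' @return RMSE in Hz, or `NA_real_` when undefined.
#' @examples
#' s <- structure(list(block_id = 1, instructed_rate_hz = 1, onset_s = 0,
#'                     duration_s = 30, tap_times_s = c(0, 1, 1.25)),
#'                class = "tap_stream")
#' rmse_score(s, 1)  # sqrt(9/2)
#' @export
rmse_score <- function(streams, instructed_rate_hz) {
  streams <- as_stream_list(streams)
  rates <- vapply(streams, function(s) s$instructed_rate_hz, numeric(1))
  if (any(rates != instructed_rate_hz))
    stop("all streams must share the instructed rate")
  err <- unlist(lapply(streams, function(s) {
    if (length(s$tap_times_s) < 2) return(numeric(0))
    gaps <- diff(s$tap_times_s)
    keep <- round(gaps * instructed_rate_hz) - 1 < 1  # not a missed-tap gap
    (1 / gaps[keep]) - instructed_rate_hz
  }))
  if (!length(err)) return(NA_real_)
  sqrt(mean(err^2))
}

#' Missed-tap fraction
#'
#' Prolonged inactivity is quantified from the inter-tap gaps of each block,
#' including the edge gaps from block start to the first tap and from the
#' last tap to block end. Each gap `dt` contributes
#' `max(0, round(dt * rate) - 1)` missed taps; a block with no taps at all
#' contributes its full complement of ideal taps (total inactivity). The
#' fraction is total missed over total ideal taps
#' (`duration * rate` summed over blocks).
#'
#' @inheritParams rmse_score
#' @return fraction of missed taps (>= 0).
#' @export
missed_tap_fraction <- function(streams, instructed_rate_hz) {
  streams <- as_stream_list(streams)
  missed <- 0
  ideal <- 0
  for (s in streams) {
    if (s$duration_s <= 0) stop("zero-duration block")
    if (s$instructed_rate_hz != instructed_rate_hz)
      stop("all streams must share the instructed rate")
    n_ideal <- s$duration_s * instructed_rate_hz
    ideal <- ideal + n_ideal
    tt <- s$tap_times_s
    if (!length(tt)) {
      missed <- missed + n_ideal
      next
    }
    gaps <- c(tt[1] - s$onset_s, diff(tt), s$onset_s + s$duration_s - tt[length(tt)])
    missed <- missed + sum(pmax(0, round(gaps * instructed_rate_hz) - 1))
  }
  missed / ideal
}

#' Per-run tapping score
#'
#' Pools all blocks of one instructed speed within a run into a single score.
#'
#' @inheritParams rmse_score
#' @param run_index run number (1, 2, 5 or 6 in the study design).
#' @return object of class `tap_score`: data.frame with `run_index`,
#'   `rate_hz`, `rmse_hz`, `missed_fraction`, `n_taps`.
#' @export
tap_score <- function(streams, instructed_rate_hz, run_index = NA_integer_) {
  streams <- as_stream_list(streams)
  out <- data.frame(
    run_index = run_index, rate_hz = instructed_rate_hz,
    rmse_hz = rmse_score(streams, instructed_rate_hz),
    missed_fraction = missed_tap_fraction(streams, instructed_rate_hz),
    n_taps = sum(vapply(streams, function(s) length(s$tap_times_s), numeric(1))))
  class(out) <- c("tap_score", class(out))
  out
}

#' Pre/post-neurofeedback tapping improvement
#'
#' The improvement score is the RMSE difference between the tapping run just
#' before the imagery neurofeedback (run 2) and the one just after (run 5), at
#' the same instructed speed. Positive values mean the error decreased.
#'
#' @param score_run2,score_run5 `tap_score` rows for runs 2 and 5.
#' @return object of class `improvement_score`: data.frame with `rate_hz`,
#'   `delta_rmse_hz`.
#' @export
improvement_score <- function(score_run2, score_run5) {
  if (score_run2$rate_hz != score_run5$rate_hz)
    stop("improvement scores compare runs at the same instructed rate")
  out <- data.frame(rate_hz = score_run2$rate_hz,
                    delta_rmse_hz = score_run2$rmse_hz - score_run5$rmse_hz)
  class(out) <- c("improvement_score", class(out))
  out
}
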