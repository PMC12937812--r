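#' Generate a synthetic tap stream for one block
#'
#' Taps are placed at the nominal interval `1/rate_hz` with additive Gaussian
#' timing jitter; each nominal tap is independently dropped with probability
#' `miss_prob`. Jittered taps falling outside the block are clipped away and
#' strict temporal ordering is enforced.
#'
#' @param rate_hz instructed tapping rate (> 0).
#' @param timing_sd_s standard deviation of tap-timing jitter in seconds.
#' @param miss_prob probability that a nominal tap is missed, in `[0, 1]`.
#' @param onset_s block onset (s).
#' @param duration_s block duration (s), must be positive.
#' @param seed integer seed; the stream is deterministic given the seed.
#' @param block_id identifier carried through to behavioral scoring.
#' @return object of class `tap_stream`: a list with `block_id`,
#'   `instructed_rate_hz`, `onset_s`, `duration_s`, `tap_times_s`.
#' @examples
#' s <- generate_tap_stream(1, 0, 0, 0, 30, seed = 1)
#' length(s$tap_times_s)  # 30 taps exactly 1 s apart
#' @export
generate_tap_stream <- function(rate_hz, timing_sd_s, miss_prob,
                                onset_s, duration_s, seed = NULL,
                                block_id = 1L) {
  stopifnot(rate_hz > 0, timing_sd_s >= 0, miss_prob >= 0, miss_prob <= 1)
  if (duration_s <= 0) stop("block duration must be positive")
  with_seed(seed, {
    n_nominal <- floor(duration_s * rate_hz + 1e-9)
    nominal <- onset_s + seq_len(n_nominal) / rate_hz
    kept <- stats::runif(n_nominal) >= miss_prob
    times <- nominal[kept]
    if (timing_sd_s > 0 && length(times))
      times <- times + stats::rnorm(length(times), 0, timing_sd_s)
    times <- sort(times[times >= onset_s & times <= onset_s + duration_s])
    if (length(times) > 1) times <- times[c(TRUE, diff(times) > 0)]
    structure(list(block_id = block_id, instructed_rate_hz = rate_hz,
                   onset_s = onset_s, duration_s = duration_s,
                   tap_times_s = times),
              class = "tap_stream")
  })
}
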