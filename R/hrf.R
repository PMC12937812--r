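#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF is modeled as the difference of two gamma densities: a
#' positive lobe peaking around 5 s and a later undershoot, with a
#' peak-to-undershoot ratio of 6 and 32 s of support. The kernel is
#' peak-normalized so that its maximum is 1.
#'
#' @param dt_s sampling interval in seconds (e.g. the TR, or a finer microtime).
#' @param duration_s kernel support in seconds (default 32).
#' @param peak_delay,undershoot_delay gamma delays in seconds (defaults 6, 16).
#' @param peak_disp,undershoot_disp gamma dispersions (defaults 1, 1).
#' @param ratio peak-to-undershoot amplitude ratio (default 6).
#' @return numeric vector of kernel values sampled at `seq(0, duration_s, dt_s)`.
#' @examples
#' h <- canonical_hrf(0.1)
#' seq(0, 32, 0.1)[which.max(h)]  # peak near 5 s
#' @export
canonical_hrf <- function(dt_s, duration_s = 32, peak_delay = 6,
                          undershoot_delay = 16, peak_disp = 1,
                          undershoot_disp = 1, ratio = 6) {
  stopifnot(dt_s > 0)
  f <- function(t)
    stats::dgamma(t, shape = peak_delay / peak_disp, scale = peak_disp) -
      stats::dgamma(t, shape = undershoot_delay / undershoot_disp,
                    scale = undershoot_disp) / ratio
  # normalize by the continuous peak so sampled values do not depend on dt
  pk <- stats::optimize(f, c(0, undershoot_delay), maximum = TRUE)$objective
  f(seq(0, duration_s, by = dt_s)) / pk
}

#' Convolve a stimulus vector with an HRF kernel
#'
#' Discrete causal convolution truncated to the length of the input, used to
#' build both the planted BOLD signal and GLM design columns.
#'
#' @param u stimulus time series (boxcar or stick function), one value per bin.
#' @param kernel HRF kernel sampled on the same time grid.
#' @return numeric vector, same length as `u`.
#' @export
convolve_hrf <- function(u, kernel) {
  n <- length(u)
  if (n == 0L) return(numeric(0))
  out <- stats::convolve(u, rev(kernel), type = "open")
  out[seq_len(n)]
}
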