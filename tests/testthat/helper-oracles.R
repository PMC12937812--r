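# Brute-force oracles, written independently of the package implementation:
# plain loops over taps and kernel bins, no shared helpers.

brute_rmse <- function(streams, rate) {
  if (inherits(streams, "tap_stream")) streams <- list(streams)
  errs <- c()
  for (s in streams) {
    tt <- s$tap_times_s
    if (length(tt) < 2) next
    for (i in 2:length(tt)) {
      gap <- tt[i] - tt[i - 1]
      n_missed <- max(0, round(gap * rate) - 1)
      if (n_missed >= 1) next  # inactivity: scored by the missed-tap metric
      errs <- c(errs, 1 / gap - rate)
    }
  }
  if (!length(errs)) return(NA_real_)
  sqrt(sum(errs^2) / length(errs))
}

brute_missed_fraction <- function(streams, rate) {
  if (inherits(streams, "tap_stream")) streams <- list(streams)
  missed <- 0; ideal <- 0
  for (s in streams) {
    ideal <- ideal + s$duration_s * rate
    tt <- s$tap_times_s
    if (!length(tt)) { missed <- missed + s$duration_s * rate; next }
    gaps <- c(tt[1] - s$onset_s, if (length(tt) > 1) diff(tt),
              s$onset_s + s$duration_s - tt[length(tt)])
    for (g in gaps) missed <- missed + max(0, round(g * rate) - 1)
  }
  missed / ideal
}

direct_convolve <- function(u, h) {
  n <- length(u)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (s in seq_len(t)) {
      k <- t - s + 1
      if (k <= length(h)) acc <- acc + u[s] * h[k]
    }
    out[t] <- acc
  }
  out
}

# rank with average ties, by explicit counting
brute_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    r[i] <- less + (eq + 1) / 2
  }
  r
}

brute_spearman <- function(x, y) {
  rx <- brute_rank(x); ry <- brute_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# exact two-sided signed-rank p by enumerating all sign assignments
exact_wilcoxon_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- brute_rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  Ws <- vapply(0:(2^n - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:n]
    sum(r[signs == 1])
  }, numeric(1))
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

make_tap_stream_manual <- function(times, rate, onset, duration, block_id = 1) {
  structure(list(block_id = block_id, instructed_rate_hz = rate,
                 onset_s = onset, duration_s = duration,
                 tap_times_s = times), class = "tap_stream")
}

random_stream <- function(rate = sample(c(1, 4), 1), duration = 30) {
  nt <- rpois(1, duration * rate * 0.9)
  times <- sort(runif(nt, 0, duration))
  times <- times[c(TRUE, diff(times) > 1e-6)]
  make_tap_stream_manual(times, rate, 0, duration)
}
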