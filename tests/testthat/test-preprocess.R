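flat_masks <- function(g = c(6L, 6L, 4L)) {
  make_masks(g, array(TRUE, g), array(FALSE, g))
}

test_that("offline preprocessing removes a planted linear trend exactly", {
  g <- c(6L, 6L, 4L); nv <- prod(g); nt <- 100
  slope <- runif(nv, -0.1, 0.1)
  Y <- 50 + outer(slope, seq_len(nt))
  run <- volume_series(Y, g, 2)
  out <- offline_preprocess(run, blur_fwhm_voxels = 0)
  # residual mean and refit slope are machine zero per voxel
  expect_lt(max(abs(rowMeans(out$data))), 1e-8)
  t_c <- seq_len(nt) - mean(seq_len(nt))
  refit <- drop(out$data %*% t_c) / sum(t_c^2)
  expect_lt(max(abs(refit)), 1e-8)
})

test_that("with no nuisance structure the output is just the blurred input", {
  g <- c(6L, 6L, 4L); nv <- prod(g); nt <- 60
  set.seed(2)
  Y <- matrix(rnorm(nv * nt), nv, nt)
  Yc <- Y - rowMeans(Y)
  t_c <- seq_len(nt) - mean(seq_len(nt))
  Yc <- Yc - outer(drop(Yc %*% t_c) / sum(t_c^2), t_c)  # detrended by hand
  out <- offline_preprocess(volume_series(Y, g, 2), blur_fwhm_voxels = 1.5)
  expect_equal(out$data, gaussian_blur(Yc, g, 1.5), tolerance = 1e-10)
})

test_that("a singular nuisance design is rejected with a diagnostic", {
  g <- c(4L, 4L, 2L); nt <- 40
  run <- volume_series(matrix(rnorm(prod(g) * nt), ncol = nt), g, 2)
  motion <- cbind(seq_len(nt), matrix(0, nt, 5))  # duplicates the trend
  expect_error(offline_preprocess(run, motion), "singular|collinear")
})

test_that("blurred impulse has the configured FWHM within half a voxel", {
  g <- c(17L, 17L, 11L)
  x <- numeric(prod(g)); ctr <- c(9, 9, 6)
  x[ctr[1] + (ctr[2] - 1) * 17 + (ctr[3] - 1) * 17 * 17] <- 1
  for (fwhm in c(1.5, 2, 3)) {
    b <- array(gaussian_blur(x, g, fwhm), g)
    prof <- b[, 9, 6]
    half <- max(prof) / 2
    above <- which(prof >= half)
    # linear interpolation at the crossings
    lo <- min(above); hi <- max(above)
    xl <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
    xr <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
    expect_equal(xr - xl, fwhm, tolerance = 0.5)
  }
})

test_that("online residual is near zero when history is on the same trend", {
  g <- c(4L, 4L, 2L); nv <- prod(g)
  slope <- runif(nv, -0.2, 0.2)
  h <- 30
  hist <- 10 + outer(slope, seq_len(h))
  newv <- 10 + slope * (h + 1)
  res <- online_preprocess(newv, hist)
  expect_lt(max(abs(res)), 1e-8)
})

test_that("degenerate histories follow the defined fallbacks", {
  v <- rnorm(32)
  expect_identical(online_preprocess(v, NULL), v)
  hist <- matrix(rnorm(32 * 3), 32, 3)
  expect_equal(online_preprocess(v, hist), v - rowMeans(hist))
})

test_that("online residuals converge to the offline residuals", {
  # stationary noiseless nuisance-only data: both pathways must agree at the
  # end of a long history
  g <- c(4L, 4L, 2L); nv <- prod(g); nt <- 201
  set.seed(8)
  slope <- runif(nv, -0.05, 0.05)
  motion <- apply(matrix(rnorm(nt * 6, 0, 0.02), nt, 6), 2, cumsum)
  coupling <- matrix(rnorm(nv * 6, 0, 0.1), nv, 6)
  Y <- 100 + outer(slope, seq_len(nt)) + coupling %*% t(motion)
  run <- volume_series(Y, g, 2)
  on <- online_replay(run, motion, blur_fwhm_voxels = 0)
  off <- offline_preprocess(run, motion, blur_fwhm_voxels = 0)
  expect_lt(max(abs(on$data[, nt] - off$data[, nt])), 1e-6)
})

test_that("task-protected online regression matches offline on task data", {
  # with a planted response and no noise, late-run online residuals follow
  # the offline convention
  ms <- flat_masks()
  sched <- make_tapping_schedule(seed = 11)
  truth <- make_ground_truth(ms, n_runs = 1, n_tr = 210,
                             amplitudes = c(tap1Hz = 1, tap4Hz = 1),
                             noise_sd = 0, drift_sd = 0.01,
                             motion_step_sd = 0, motion_coupling_sd = 0,
                             motor_voxels = which(ms$analysis_mask)[1:6],
                             seed = 3)
  run <- generate_bold_run(sched, ms, truth, seed = 1)
  on <- online_replay(run, NULL, schedule = sched, blur_fwhm_voxels = 0)
  off <- offline_preprocess(run, NULL, blur_fwhm_voxels = 0)
  late <- 150:210
  expect_lt(max(abs(on$data[, late] - off$data[, late])), 0.05)
})
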