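grid_s <- c(5L, 5L, 4L)

test_that("design columns equal the convolution oracle and pass rank checks", {
  b <- data.frame(block_id = 1, condition = "ITAP", onset_s = 0, duration_s = 30)
  # single 30 s block (practice-free schedule is invalid, so build by hand)
  cond <- c(rep("ITAP", 15), rep(NA, 45))
  hrf <- canonical_hrf(2)
  sched <- structure(list(blocks = b, run_kind = "imagery", tr_s = 2,
                          total_duration_s = 120), class = "block_schedule")
  X <- build_design(60, 2, schedule = sched, conditions = "ITAP")
  u <- as.numeric(!is.na(cond) & cond == "ITAP")
  expect_lt(max(abs(X[, "ITAP"] - direct_convolve(u, hrf))), 1e-9)
  expect_true(all(c("intercept", "drift1") %in% colnames(X)))

  # an empty event regressor is an all-zero column, caught by the rank check
  expect_error(build_design(60, 2, events = list(a = 1:5, none = integer(0))),
               "rank-deficient.*none")
  # disjoint event sets are not collinear
  X2 <- build_design(120, 2, events = list(a = c(5, 30, 60), b = c(15, 45, 90)))
  expect_lt(abs(cor(X2[, "a"], X2[, "b"])), 1)
})

test_that("noiseless OLS recovers planted effects exactly", {
  set.seed(1)
  X <- build_design(80, 2, events = list(a = c(5, 25, 50), b = c(15, 40, 65)))
  beta <- matrix(rnorm(prod(grid_s) * ncol(X)), ncol = ncol(X))
  Y <- beta %*% t(X)
  run <- volume_series(Y, grid_s, 2)
  cm <- fit_first_level(run, X, c(a = 1, b = -1))
  expect_lt(max(abs(cm$estimate - (beta[, 1] - beta[, 2]))), 1e-9)
  # equal planted betas cancel under [1, -1]
  Y2 <- beta[, c(1, 1, 3, 4)] %*% t(X)
  cm2 <- fit_first_level(volume_series(Y2, grid_s, 2), X, c(a = 1, b = -1))
  expect_lt(max(abs(cm2$estimate)), 1e-9)
  # residuals of a noisy fit are orthogonal to every design column
  Yn <- Y + matrix(rnorm(length(Y)), nrow(Y))
  cmn <- fit_first_level(volume_series(Yn, grid_s, 2), X, c(a = 1, b = -1))
  E <- Yn - t(X %*% cmn$betas)
  expect_lt(max(abs(crossprod(X, t(E)))), 1e-6)
})

test_that("beta variability matches the analytic OLS covariance", {
  set.seed(42)
  X <- build_design(60, 2, events = list(a = c(4, 20, 40)))
  cvec <- c(a = 1)
  cv_full <- numeric(ncol(X)); names(cv_full) <- colnames(X); cv_full["a"] <- 1
  sigma <- 2
  an_sd <- sigma * sqrt(drop(t(cv_full) %*% solve(crossprod(X)) %*% cv_full))
  ests <- replicate(500, {
    Y <- matrix(rnorm(4 * 60, 0, sigma), 4, 60)
    fit_first_level(volume_series(Y, c(2L, 2L, 1L), 2), X, cvec)$estimate
  })
  expect_equal(sd(as.vector(ests)), an_sd, tolerance = 0.1 * an_sd)
})

test_that("group one-sample t behaves like t(n-1) under the null", {
  n <- 12
  set.seed(3)
  M <- matrix(rnorm(10000 * n), ncol = n)
  sm <- group_one_sample(M, grid_shape = c(100L, 100L, 1L))
  expect_equal(sm$df, n - 1)
  ks <- suppressWarnings(ks.test(sm$t, pt, df = n - 1))
  expect_gt(ks$p.value, 0.01)
  # identical maps have zero variance: undefined, not infinite
  same <- matrix(1, 50, 5)
  expect_true(all(is.na(group_one_sample(same, grid_shape = c(50L, 1L, 1L))$t)))
})

test_that("one-sample detection rate matches noncentral-t power", {
  n <- 14; delta <- 1; sigma <- 1
  set.seed(9)
  M <- matrix(rnorm(4000 * n, delta, sigma), ncol = n)
  sm <- group_one_sample(M, grid_shape = c(4000L, 1L, 1L))
  tcrit <- qt(0.999, n - 1)
  rate <- mean(sm$t > tcrit)
  power <- pt(tcrit, n - 1, ncp = delta / (sigma / sqrt(n)), lower.tail = FALSE)
  expect_equal(rate, power, tolerance = 3 * sqrt(power * (1 - power) / 4000) + 0.01)
})

test_that("covariate maps isolate the improvement coefficient", {
  set.seed(5)
  n <- 16
  ctrl <- rnorm(n)
  delta <- rnorm(n)
  M <- matrix(rnorm(2000 * n), ncol = n) + outer(rep(1, 2000), 2 * ctrl)
  sm <- group_covariate(M, delta, ctrl, grid_shape = c(2000L, 1L, 1L))
  expect_equal(sm$df, n - 3)
  # effect carried entirely by the control: improvement-null rejection near nominal
  rej <- mean(abs(sm$t) > qt(0.9995, n - 3), na.rm = TRUE)
  expect_lt(rej, 0.01)
  expect_lt(abs(mean(sm$t)), 0.1)
  expect_error(group_covariate(M, ctrl, ctrl), "collinear")
  # constant control reduces to the two-column fit exactly
  M2 <- matrix(rnorm(200 * n), ncol = n)
  sm2 <- group_covariate(M2, delta, rep(1, n), grid_shape = c(200L, 1L, 1L))
  X <- cbind(1, delta)
  B <- solve(crossprod(X), crossprod(X, t(M2)))
  res <- t(M2) - X %*% B
  se <- sqrt(colSums(res^2) / (n - 2) * solve(crossprod(X))[2, 2])
  expect_equal(sm2$beta, B[2, ], tolerance = 1e-10)
  expect_equal(sm2$t, unname(B[2, ] / se), tolerance = 1e-10)
  expect_equal(sm2$df, n - 2)
})
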