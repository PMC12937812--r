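test_that("one-sample t agrees between raw and summary inputs", {
  set.seed(4)
  x <- rnorm(16, 55, 9)
  a <- one_sample_t(x, mu = 50)
  b <- one_sample_t(mean = mean(x), sd = sd(x), n = 16, mu = 50)
  expect_equal(a$value, b$value)
  expect_equal(a$p_two_tailed, b$p_two_tailed)
  expect_equal(a$df, 15)
  flat <- one_sample_t(mean = 50, sd = 8, n = 16, mu = 50)
  expect_equal(flat$value, 0)
  expect_equal(flat$p_two_tailed, 1)
  expect_true(is.na(one_sample_t(mean = 50, sd = 0, n = 16, mu = 50)$value))
})

test_that("one-sample t is location-scale equivariant", {
  set.seed(6)
  x <- rnorm(12, 3, 2)
  t0 <- one_sample_t(x, mu = 2)$value
  expect_equal(one_sample_t(x + 10, mu = 12)$value, t0)
  expect_equal(one_sample_t(3 * x, mu = 6)$value, t0)
})

test_that("two-level repeated-measures F equals the squared paired t", {
  set.seed(8)
  for (rep in 1:5) {
    y <- matrix(rnorm(24, 10), 12, 2)
    out <- rm_anova(y, factor_names = "cond")
    tt <- t.test(y[, 1], y[, 2], paired = TRUE)
    expect_equal(out$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(out$p, tt$p.value, tolerance = 1e-9)
    expect_equal(out$epsilon, 1)
    expect_identical(out$correction, "none")
  }
})

test_that("two-factor RM-ANOVA matches car::Anova including sphericity handling", {
  skip_if_not_installed("car")
  set.seed(10)
  n <- 16; a <- 4; b <- 2
  cells <- array(rnorm(n * a * b, 5), c(n, a, b))
  cells[, 2, ] <- cells[, 2, ] + 0.8      # a run effect
  cells[, , 1] <- cells[, , 1] + cells[, 1, 1] * 0.3  # break sphericity a bit
  ours <- rm_anova(cells, factor_names = c("run", "speed"))

  Y <- matrix(aperm(cells, c(1, 3, 2)), n, a * b)
  idata <- expand.grid(speed = factor(1:b), run = factor(1:a))
  mod <- lm(Y ~ 1)
  an <- car::Anova(mod, idata = idata, idesign = ~ run * speed, type = 3)
  s <- suppressWarnings(summary(an, multivariate = FALSE))
  uni <- s$univariate.tests
  for (eff in c("run", "speed", "run:speed")) {
    ours_row <- ours[ours$effect == eff, ]
    expect_equal(ours_row$F, uni[eff, "F value"], tolerance = 1e-8)
  }
  # Greenhouse-Geisser epsilon and Mauchly p for the >2-level factor
  expect_equal(ours[ours$effect == "run", "epsilon"],
               unname(s$pval.adjustments["run", "GG eps"]), tolerance = 1e-8)
  expect_equal(ours[ours$effect == "run", "mauchly_p"],
               unname(s$sphericity.tests["run", "p-value"]), tolerance = 1e-6)
})

test_that("Greenhouse-Geisser correction engages only when Mauchly rejects", {
  set.seed(12)
  n <- 14; a <- 4
  # strongly non-spherical: one condition much more variable
  cells <- matrix(rnorm(n * a), n, a)
  cells[, 1] <- cells[, 1] * 6
  out <- rm_anova(cells, factor_names = "run")
  expect_lt(out$mauchly_p, 0.05)
  expect_identical(out$correction, "greenhouse_geisser")
  expect_lt(out$df1, a - 1 + 1e-12)
  expect_lt(out$epsilon, 1)
  expect_gte(out$epsilon, 1 / (a - 1) - 1e-9)
})

test_that("RM-ANOVA rejects unbalanced input", {
  cells <- matrix(rnorm(20), 10, 2)
  cells[1, 1] <- NA
  expect_error(rm_anova(cells), "missing|balanced")
})

test_that("Wilcoxon signed-rank matches conventions and edge cases", {
  expect_true(is.na(wilcoxon_signed_rank(1:5, 1:5)$value))
  set.seed(14)
  for (rep in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    z1 <- wilcoxon_signed_rank(x, y)$value
    z2 <- wilcoxon_signed_rank(y, x)$value
    expect_equal(z1, -z2)
    p <- wilcoxon_signed_rank(x, y)$p_two_tailed
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("Wilcoxon normal approximation tracks exact enumeration for small n", {
  # the continuity-corrected normal approximation has a worst-case error of
  # about 0.036 at n = 6 that shrinks below 0.02 by n = 9; check both the
  # small-n ceiling and the n = 10 bound
  set.seed(16)
  worst_small <- 0
  for (rep in 1:40) {
    n <- sample(6:9, 1)
    x <- rnorm(n); y <- rnorm(n)
    worst_small <- max(worst_small,
                       abs(wilcoxon_signed_rank(x, y)$p_two_tailed -
                             exact_wilcoxon_p(x, y)))
  }
  expect_lt(worst_small, 0.04)
  worst10 <- 0
  for (rep in 1:40) {
    x <- rnorm(10); y <- rnorm(10)
    worst10 <- max(worst10,
                   abs(wilcoxon_signed_rank(x, y)$p_two_tailed -
                         exact_wilcoxon_p(x, y)))
  }
  expect_lt(worst10, 0.02)
})

test_that("Spearman handles monotone, reversed, tied and constant input", {
  expect_equal(spearman_rho(1:8, (1:8)^3)$value, 1)
  expect_equal(spearman_rho(1:8, -(1:8))$value, -1)
  expect_true(is.na(spearman_rho(rep(2, 5), rnorm(5))$value))
  set.seed(18)
  for (rep in 1:100) {
    n <- sample(5:15, 1)
    x <- sample(1:4, n, replace = TRUE)  # heavy ties
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y)$value, brute_spearman(x, y), tolerance = 1e-12)
  }
})

test_that("tests are invariant to reordering the paired samples", {
  set.seed(20)
  x <- rnorm(12); y <- rnorm(12)
  perm <- sample(12)
  expect_equal(wilcoxon_signed_rank(x, y)$value,
               wilcoxon_signed_rank(x[perm], y[perm])$value)
  expect_equal(spearman_rho(x, y)$value, spearman_rho(x[perm], y[perm])$value)
  expect_equal(one_sample_t(x)$value, one_sample_t(x[perm])$value)
})
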