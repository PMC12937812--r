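test_result <- function(statistic, value, df, p, correction = "none",
                        extra = list()) {
  structure(c(list(statistic = statistic, value = value, df = df,
                   p_two_tailed = p, correction = correction), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(signif(unlist(x$df), 4), collapse = ", ")
  cat(sprintf("%s = %.4g, df = %s, two-tailed p = %.4g (%s)\n",
              x$statistic, x$value, dfs, x$p_two_tailed, x$correction))
  invisible(x)
}

#' One-sample t test from raw data or summary statistics
#'
#' Accepts either a raw sample or the triplet (mean, sd, n); both entry
#' points give identical results, which makes it possible to recompute
#' printed group results from reported summary statistics alone.
#'
#' @param x raw sample (optional).
#' @param mean,sd,n summary statistics (used when `x` is missing).
#' @param mu null-hypothesis mean.
#' @return a `test_result` with t, df = n - 1 and the two-tailed p. A zero
#'   SD yields an undefined result (`NA` statistic).
#' @examples
#' one_sample_t(mean = 58.3, sd = 10.7, n = 16, mu = 50)
#' @export
one_sample_t <- function(x = NULL, mean = NULL, sd = NULL, n = NULL, mu = 0) {
  if (!is.null(x)) {
    n <- length(x)
    mean <- base::mean(x)
    sd <- stats::sd(x)
  }
  stopifnot(n >= 2)
  if (is.na(sd) || sd <= 0)
    return(test_result("t", NA_real_, n - 1, NA_real_))
  tval <- (mean - mu) / (sd / sqrt(n))
  test_result("t", tval, n - 1, 2 * stats::pt(-abs(tval), n - 1))
}

# Orthonormal contrast matrix over p levels (helmert-based).
orthonormal_contrasts <- function(p) {
  C <- stats::contr.helmert(p)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Univariate RM effect from an n x p matrix of within-subject scores and an
# orthonormal contrast matrix C (p x q): F, dfs, GG epsilon, Mauchly test.
rm_effect <- function(Y, C) {
  Z <- Y %*% C
  n <- nrow(Z); q <- ncol(Z)
  zbar <- colMeans(Z)
  ss_eff <- n * sum(zbar^2)
  E <- crossprod(sweep(Z, 2, zbar))
  ss_err <- sum(diag(E))
  df1 <- q; df2 <- q * (n - 1)
  Fv <- (ss_eff / df1) / (ss_err / df2)
  Sigma <- E / (n - 1)
  eps <- sum(diag(Sigma))^2 / (q * sum(Sigma^2))
  mauchly_p <- NA_real_
  if (q > 1) {
    mauchly_p <- tryCatch(
      suppressWarnings(stats::mauchly.test(stats::lm(Y ~ 1), T = t(C))$p.value),
      error = function(e) 0)
    if (is.nan(mauchly_p)) mauchly_p <- NA_real_  # singular contrast covariance
  }
  list(F = Fv, df1 = df1, df2 = df2, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       epsilon = eps, mauchly_p = mauchly_p)
}

#' Repeated-measures ANOVA with sphericity handling
#'
#' One- or two-factor fully within-subject ANOVA on complete balanced data.
#' For every within factor (and the interaction) with more than two levels,
#' Mauchly's sphericity test is run and, when it rejects at 0.05, the
#' Greenhouse-Geisser epsilon is applied to the degrees of freedom; with
#' two-level factors sphericity is vacuous and no correction applies.
#'
#' @param cells numeric array `n_subjects x levels_A` (one factor) or
#'   `n_subjects x levels_A x levels_B` (two factors), one cell score per
#'   subject and condition.
#' @param factor_names names for the one or two within factors.
#' @param sphericity_alpha Mauchly rejection level gating the correction.
#' @return data.frame with one row per effect: `effect`, `F`, `df1`, `df2`
#'   (corrected where applicable), `p`, `epsilon`, `mauchly_p`, `correction`.
#' @export
rm_anova <- function(cells, factor_names = NULL, sphericity_alpha = 0.05) {
  dims <- dim(cells)
  if (is.null(dims) || length(dims) < 2 || length(dims) > 3)
    stop("cells must be subjects x A or subjects x A x B")
  if (anyNA(cells)) stop("missing cells are not supported (balanced design required)")
  n <- dims[1]; a <- dims[2]; b <- if (length(dims) == 3) dims[3] else NULL
  factor_names <- factor_names %||% if (is.null(b)) "A" else c("A", "B")
  # flatten to n x p with A slowest, B fastest
  Y <- if (is.null(b)) cells else matrix(aperm(cells, c(1, 3, 2)), n, a * b)
  PA <- orthonormal_contrasts(a)
  effects <- list()
  if (is.null(b)) {
    effects[[factor_names[1]]] <- PA
  } else {
    PB <- orthonormal_contrasts(b)
    ja <- matrix(1 / sqrt(a), a, 1)
    jb <- matrix(1 / sqrt(b), b, 1)
    effects[[factor_names[1]]] <- kronecker(PA, jb)
    effects[[factor_names[2]]] <- kronecker(ja, PB)
    effects[[paste(factor_names, collapse = ":")]] <- kronecker(PA, PB)
  }
  rows <- lapply(names(effects), function(nm) {
    e <- rm_effect(Y, effects[[nm]])
    correct <- !is.na(e$mauchly_p) && e$mauchly_p < sphericity_alpha
    if (correct) {
      df1 <- e$epsilon * e$df1
      df2 <- e$epsilon * e$df2
      p <- stats::pf(e$F, df1, df2, lower.tail = FALSE)
    } else {
      df1 <- e$df1; df2 <- e$df2; p <- e$p
    }
    data.frame(effect = nm, F = e$F, df1 = df1, df2 = df2, p = p,
               epsilon = e$epsilon, mauchly_p = e$mauchly_p,
               correction = if (correct) "greenhouse_geisser" else "none")
  })
  do.call(rbind, rows)
}

#' Wilcoxon signed-rank test (normal approximation with tie and continuity
#' correction)
#'
#' Zero differences are dropped, absolute differences are mid-ranked, and
#' the positive-rank sum is standardized with the tie-corrected variance and
#' a 0.5 continuity correction, yielding the Z statistic as reported by
#' common statistics packages. All pairs equal yields an undefined result.
#'
#' @param x,y paired samples of equal length.
#' @return a `test_result` with the Z value and two-tailed normal p.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(test_result("Z", NA_real_, NA_real_, NA_real_))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(test_result("Z", NA_real_, n, NA_real_))
  z <- if (W == mu) 0 else (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
  test_result("Z", z, n, 2 * stats::pnorm(-abs(z)),
              extra = list(W = W, n_nonzero = n))
}

#' Spearman rank correlation with t-approximation p value
#'
#' Ranks (average ties), Pearson-correlates the ranks, and converts rho to a
#' two-tailed p through the t approximation with n - 2 df. Constant input
#' yields an undefined result.
#'
#' @param x,y equal-length samples, n >= 3.
#' @return a `test_result` with rho (`value`) and the p value.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(test_result("rho", NA_real_, length(x) - 2, NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  test_result("rho", rho, n - 2, p)
}
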