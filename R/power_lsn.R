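# Post-hoc power and least significant number for a tested linear-model
# term, following the retrospective-power conventions of classical
# least-squares software: the observed effect size is taken at face value
# (squared effect size = SSH/N, error variance = MSE) and projected onto
# the noncentral F distribution.

check_df <- function(df1, df2) {
  if (!is.finite(df1) || df1 < 1 || df1 != round(df1)) {
    stop("df1 must be a positive integer", call. = FALSE)
  }
  if (!is.finite(df2) || df2 < 1) stop("df2 must be >= 1", call. = FALSE)
}

#' Post-hoc power of a tested linear-model term
#'
#' Power at the observed sample size: with noncentrality
#' \code{lambda = SSH / MSE}, power = P[F'(df1, df2, lambda) >
#' F_crit(alpha, df1, df2)] where df2 = n - n_coefficients. A zero
#' hypothesis sum of squares gives power exactly equal to \code{alpha}
#' (the central case).
#'
#' @param ss_hyp Hypothesis sum of squares of the tested term (partial,
#'   i.e. F * MSE for a 1-df term).
#' @param ms_error Residual mean square of the fitted model.
#' @param n Number of observations used in the fit.
#' @param df1 Numerator degrees of freedom of the tested term.
#' @param n_coefficients Number of fitted coefficients (including the
#'   intercept); df2 = n - n_coefficients.
#' @param alpha Significance level (default 0.05).
#' @return Power (1 - beta) in (0, 1).
#' @export
posthoc_power <- function(ss_hyp, ms_error, n, df1 = 1, n_coefficients,
                          alpha = 0.05) {
  if (ss_hyp < 0 || ms_error <= 0) {
    stop("need ss_hyp >= 0 and ms_error > 0", call. = FALSE)
  }
  df2 <- n - n_coefficients
  check_df(df1, df2)
  lambda <- ss_hyp / ms_error
  fcrit <- stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(fcrit, df1, df2, ncp = lambda)
}

#' Least significant number of a tested linear-model term
#'
#' The smallest sample size m at which the observed effect would be
#' expected to reach significance at level \code{alpha}: the squared
#' effect size \code{delta^2 = SSH / n} and the error variance
#' \code{sigma^2 = MSE} are held fixed, the expected F at candidate size m
#' is \code{(m * delta^2 / sigma^2) / df1} with df2 recomputed as
#' \code{m - n_coefficients}, and lsn is the smallest integer m for which
#' this F meets or exceeds the critical F. The expected F is increasing
#' and the critical F decreasing in m, so the crossing is unique; it is
#' located by doubling and binary search.
#'
#' @inheritParams posthoc_power
#' @param max_n Search ceiling; an effect so small that significance is
#'   not reached by \code{max_n} raises an error.
#' @return Whole-valued numeric sample size (may exceed the 32-bit
#'   integer range for near-null effects).
#' @export
lsn <- function(ss_hyp, ms_error, n, df1 = 1, n_coefficients, alpha = 0.05,
                max_n = 1e9) {
  if (ss_hyp <= 0 || ms_error <= 0 || n <= 0) {
    stop("need ss_hyp > 0, ms_error > 0, n > 0", call. = FALSE)
  }
  check_df(df1, n - n_coefficients)
  ratio <- (ss_hyp / n) / ms_error  # delta^2 / sigma^2
  hit <- function(m) {
    (m * ratio) / df1 >= stats::qf(1 - alpha, df1, m - n_coefficients)
  }
  lo <- n_coefficients + 1
  hi <- lo
  while (!hit(hi)) {
    lo <- hi + 1
    hi <- hi * 2
    if (hi > max_n) {
      stop("lsn exceeds max_n: effect too small to reach significance",
           call. = FALSE)
    }
  }
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (hit(mid)) hi <- mid else lo <- mid + 1
  }
  lo
}

#' Append power and lsn columns to an association table
#'
#' @param results Data frame of stacked \code{assoc_result} rows.
#' @param alpha Significance level.
#' @param max_n Search ceiling passed to \code{\link{lsn}}; the pipeline
#'   default is generous because a near-null association still needs a
#'   finite lsn to be rankable (it simply ranks last).
#' @return The same data frame with \code{power} and \code{lsn} columns.
#' @export
add_power_lsn <- function(results, alpha = 0.05, max_n = 1e15) {
  results$power <- mapply(posthoc_power, results$ss_hypothesis,
                          results$ms_error, results$n_used, results$df1,
                          results$n_coefficients, MoreArgs = list(alpha = alpha))
  results$lsn <- mapply(function(ssh, mse, n, d1, k) {
    if (ssh <= 0) return(NA_real_)
    lsn(ssh, mse, n, d1, k, alpha = alpha, max_n = max_n)
  }, results$ss_hypothesis, results$ms_error, results$n_used, results$df1,
    results$n_coefficients)
  results
}
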