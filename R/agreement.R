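# Method-comparison statistics: ordinary least squares, paired t-test,
# Bland-Altman analysis with proportional-error detection, and the
# repeatability coefficient (RPC). All statistics are computed from
# closed-form formulas so the test suite can check them against the
# standard model-fitting routines as an independent oracle.

#' Ordinary least-squares line with Pearson correlation
#'
#' Regression of `y` on `x` (in method comparisons, the candidate method on
#' the gold standard). The p-value is the two-sided test of zero Pearson
#' correlation, `t = r * sqrt((n-2)/(1-r^2))` on `n - 2` df.
#'
#' @param x Predictor values (non-constant, n >= 3).
#' @param y Response values.
#' @return List with `slope`, `intercept`, `r`, `p`, `n`.
#' @export
linear_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length")
  if (n < 3L) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x is constant: regression undefined")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(slope = slope, intercept = intercept, r = r, p = p, n = n)
}

#' Two-sided paired t-test
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the paired differences `d = a - b`,
#' with `n - 1` degrees of freedom.
#'
#' @param a,b Paired measurement vectors (n >= 2).
#' @return List with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (length(b) != n) stop("a and b must have the same length")
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero-variance differences: paired t-test undefined")
  tstat <- mean(d) / (sdd / sqrt(n))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1),
       df = n - 1L, mean_diff = mean(d))
}

#' Bland-Altman agreement analysis with repeatability coefficient
#'
#' Differences `d = a - b` are analysed against means `m = (a+b)/2`. A
#' significant Pearson correlation of `d` with `m` (at `alpha`) indicates a
#' proportional error; the mean difference indicates a systematic error.
#' The repeatability coefficient is `2 * sd(d)`, or, under a proportional
#' error, `2 * sd` of the residuals of the OLS regression of `d` on `m`.
#' Identical methods (`sd(d) == 0`) are a legitimate degenerate input:
#' no proportional error, RPC 0, paired-t p undefined (`NA`).
#'
#' @param a,b Paired measurement vectors (n >= 3). In the regression
#'   summary, `b` is regressed on `a` (gold standard on the x-axis).
#' @param alpha Significance level for the proportional-error test
#'   (default 0.05).
#' @return Object of class `agreement_report`: `n`, `slope`, `intercept`,
#'   `r`, `p_regression` (b on a); `mean_diff`, `sd_diff`, `p_paired_t`;
#'   `p_proportional`, `proportional_error`, `rpc`; `loa_lower`,
#'   `loa_upper` (mean_diff -/+ 2 sd_diff); `alpha`.
#' @export
bland_altman <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (length(b) != n) stop("a and b must have the same length")
  if (n < 3L) stop("need at least 3 pairs")
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed")
  fit <- linear_fit(a, b)
  d <- a - b
  m <- (a + b) / 2
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  if (sd_diff == 0) {
    p_prop <- NA_real_
    proportional <- FALSE
    rpc <- 0
    p_t <- NA_real_
  } else {
    p_prop <- if (stats::sd(m) == 0) NA_real_ else linear_fit(m, d)$p
    proportional <- is.finite(p_prop) && p_prop < alpha
    rpc <- if (proportional) {
      ba <- linear_fit(m, d)
      2 * stats::sd(d - (ba$intercept + ba$slope * m))
    } else 2 * sd_diff
    p_t <- paired_t(a, b)$p
  }
  structure(list(n = n,
                 slope = fit$slope, intercept = fit$intercept,
                 r = fit$r, p_regression = fit$p,
                 mean_diff = mean_diff, sd_diff = sd_diff, p_paired_t = p_t,
                 p_proportional = p_prop, proportional_error = proportional,
                 rpc = rpc,
                 loa_lower = mean_diff - 2 * sd_diff,
                 loa_upper = mean_diff + 2 * sd_diff,
                 alpha = alpha),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement_report (n = %d)\n", x$n))
  cat(sprintf("  regression b ~ a: slope %.3f, intercept %.3f, r %.3f (p %.3g)\n",
              x$slope, x$intercept, x$r, x$p_regression))
  cat(sprintf("  mean diff %.3f +/- %.3f (paired t p %.3g)\n",
              x$mean_diff, x$sd_diff, x$p_paired_t))
  cat(sprintf("  proportional error: %s (p %.3g); RPC %.3f; LoA [%.3f, %.3f]\n",
              x$proportional_error, x$p_proportional, x$rpc,
              x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Flatten an agreement report for JSON export
#' @param report An `agreement_report`.
#' @return Named list of scalars.
#' @export
agreement_report_summary <- function(report) {
  unclass(report)
}
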