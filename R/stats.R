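#' One-sample t-test against a reference value
#'
#' Closed-form small-sample test of whether the mean of `values` differs
#' from `mu0` (default 0, the no-preference point of a discrimination
#' index): `t = (mean - mu0) / (sd / sqrt(n))` with the n-1 standard
#' deviation and a two-sided p-value from the Student t distribution on
#' n - 1 degrees of freedom.
#'
#' @param values Numeric sample, `n >= 2`, non-zero variance.
#' @param mu0 Null mean, default 0.
#' @return List of class `one_sample_t`: `t`, `df`, `p_two_sided`, `n`,
#'   `mean`, `sd`, `mu0`.
#' @export
#' @examples
#' one_sample_t(c(1, 1, 1, -1))  # t = 1, df = 3
one_sample_t <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing values in sample")
  n <- length(values)
  if (n < 2) stop("need at least 2 observations")
  s <- stats::sd(values)
  if (s == 0) stop("zero sample variance: t statistic undefined")
  t <- (mean(values) - mu0) / (s / sqrt(n))
  structure(list(t = t, df = n - 1L,
                 p_two_sided = 2 * stats::pt(-abs(t), df = n - 1),
                 n = n, mean = mean(values), sd = s, mu0 = mu0),
            class = "one_sample_t")
}

#' @export
print.one_sample_t <- function(x, ...) {
  cat(sprintf("one-sample t vs %g: t(%d) = %.4g, p = %.4g (n = %d)\n",
              x$mu0, x$df, x$t, x$p_two_sided, x$n))
  invisible(x)
}

#' Pearson correlation and simple linear regression
#'
#' Product-moment correlation of `x` and `y` together with the ordinary
#' least-squares line `y = intercept + slope * x`. The two-sided p-value
#' comes from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom; for simple regression this equals the slope's t-test, so a
#' single p is reported.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with positive
#'   variance.
#' @return List of class `pearson_fit`: `r`, `r_squared`, `slope`,
#'   `intercept`, `p`, `n`, `df`.
#' @export
pearson_and_fit <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  if (sxx == 0 || syy == 0) stop("zero variance in x or y")
  r <- sxy / sqrt(sxx * syy)
  slope <- sxy / sxx
  intercept <- my - slope * mx
  p <- if (abs(r) >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, r_squared = r^2, slope = slope,
                 intercept = intercept, p = p, n = n, df = n - 2L),
            class = "pearson_fit")
}

#' @export
print.pearson_fit <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (R^2 = %.3f), y = %.3f + %.3f x, p = %.4g (n = %d)\n",
              x$r, x$r_squared, x$intercept, x$slope, x$p, x$n))
  invisible(x)
}

#' Consistency check between a printed r and a printed R-squared
#'
#' Squares a reported Pearson correlation and rounds to 3 decimals, the
#' precision at which regression tables typically print the coefficient of
#' determination, so the two reported quantities can be cross-checked.
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @return `round(r^2, 3)`.
#' @export
#' @examples
#' r2_consistency(0.8429)  # 0.710
r2_consistency <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must not exceed 1")
  round(r^2, 3)
}
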