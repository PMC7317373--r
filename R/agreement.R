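## Method-agreement statistics used to compare two processing pipelines:
## Bland-Altman bias and limits of agreement, intraclass correlation
## ICC(2,1) (two-way random effects, absolute agreement, single measures),
## and through-origin regression.

#' Bland-Altman analysis of paired measurements
#'
#' Differences `d = x - y`: bias = mean(d), limits of agreement
#' `bias +/- 1.96 sd(d)` (sample sd, n - 1 denominator). The 95% CI of the
#' bias uses the t distribution; the 95% CI of each limit uses the
#' `sd(d) * sqrt(3/n)` normal approximation.
#'
#' @param x,y paired numeric vectors, length n >= 3.
#' @return list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `ci_bias`,
#'   `ci_loa_low`, `ci_loa_high`, `n`.
#' @export
bland_altman <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("Bland-Altman requires at least 3 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  tq <- qt(0.975, n - 1)
  ci_bias <- bias + c(-1, 1) * tq * s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  list(bias = bias, loa_low = loa[1], loa_high = loa[2], sd_diff = s,
       ci_bias = ci_bias,
       ci_loa_low = loa[1] + c(-1, 1) * 1.96 * se_loa,
       ci_loa_high = loa[2] + c(-1, 1) * 1.96 * se_loa,
       n = n)
}

#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' two-way ANOVA decomposition of an n x 2 table (subjects x raters):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with the standard F-based confidence interval. Because this is the
#' absolute-agreement form, a constant offset between raters lowers the ICC.
#'
#' @param x,y paired numeric vectors (two raters), length n >= 5.
#' @param conf confidence level.
#' @return list with `icc`, `ci_low`, `ci_high`, `n`.
#' @export
icc_agreement <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5) stop("ICC requires at least 5 pairs")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ss_total <- sum((dat - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total <= 0) stop("zero total variance")
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  ## F-based CI (Shrout & Fleiss / McGraw & Wong, absolute agreement)
  alpha <- 1 - conf
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    ((k * icc * fj + n * (1 + (k - 1) * icc) - k * icc))^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  f_obs <- msr / mse
  fl <- f_obs / qf(1 - alpha / 2, n - 1, v)
  fu <- f_obs * qf(1 - alpha / 2, v, n - 1)
  ci_low <- (fl - 1) / (fl + k - 1)
  ci_high <- (fu - 1) / (fu + k - 1)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high, n = n)
}

#' Through-origin regression slope and R-squared
#'
#' `slope = sum(xy) / sum(x^2)`; the no-intercept R^2 convention takes the
#' total sum of squares about zero:
#' `R^2 = 1 - sum((y - slope x)^2) / sum(y^2)` (stated explicitly because
#' no-intercept R^2 definitions differ in the literature).
#'
#' @param x,y numeric vectors, length >= 2, `sum(x^2) > 0`.
#' @return list with `slope`, `r2`, `n`.
#' @export
slope_through_origin <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  sxx <- sum(x^2)
  if (sxx <= 0) stop("all-zero x")
  slope <- sum(x * y) / sxx
  r2 <- 1 - sum((y - slope * x)^2) / sum(y^2)
  list(slope = slope, r2 = r2, n = length(x))
}
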