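# Agreement and consistency statistics: Bland-Altman, absolute
# differences, Welch's t, two-sample F, Pearson correlation, Williams'
# test for two dependent correlations with one variable in common, range
# truncation, and the consistency comparison of rate-of-change samples.
# Sample SDs use the n-1 denominator throughout.

check_pairs <- function(a, b, min_n = 3L) {
  if (length(a) != length(b)) stop("paired samples differ in length")
  if (length(a) < min_n) stop("need at least ", min_n, " pairs")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values in input")
  invisible(length(a))
}

#' Bland-Altman agreement analysis
#'
#' Examines the paired differences `d = a - b`: their mean, sample SD and
#' the limits of agreement `mean +/- 1.96 sd` that bracket ~95% of
#' differences under normality. The signed convention is `a - b`
#' (first argument minus second). A per-pair `(mean, difference)` table is
#' attached for the standard Bland-Altman plot.
#'
#' @param a,b paired score vectors (e.g. automatic vs standard cyst
#'   scores of the same scans), length >= 3.
#' @param truncation optional `(lo, hi)` recorded when the pairs were
#'   range-truncated beforehand (see [range_truncate()]).
#' @return An `agreement_report`: list with `n`, `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `mean_abs_diff`, `sd_abs_diff`, `truncation`
#'   and `pairs` (data frame with `mean`, `diff`).
#' @examples
#' bland_altman(c(10, 12, 8), c(11, 11, 9))
#' @export
bland_altman <- function(a, b, truncation = NULL) {
  n <- check_pairs(a, b)
  d <- a - b
  ad <- abs(d)
  structure(list(
    n = n,
    mean_diff = mean(d), sd_diff = sd(d),
    loa_low = mean(d) - 1.96 * sd(d), loa_high = mean(d) + 1.96 * sd(d),
    mean_abs_diff = mean(ad), sd_abs_diff = sd(ad),
    truncation = truncation,
    pairs = data.frame(mean = (a + b) / 2, diff = d)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n=%d, diff (a-b) %.3f +/- %.3f, LoA [%.3f, %.3f]\n",
              x$n, x$mean_diff, x$sd_diff, x$loa_low, x$loa_high))
  cat(sprintf("  |diff| %.3f +/- %.3f", x$mean_abs_diff, x$sd_abs_diff))
  if (!is.null(x$truncation))
    cat(sprintf(", truncated to [%.3g, %.3g]", x$truncation[1], x$truncation[2]))
  cat("\n")
  invisible(x)
}

#' Mean and SD of absolute pairwise differences
#'
#' @inheritParams bland_altman
#' @return Named vector `c(mean, sd)` of `|a - b|`.
#' @export
abs_diff_stats <- function(a, b) {
  check_pairs(a, b)
  d <- abs(a - b)
  c(mean = mean(d), sd = sd(d))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value.
#'
#' @param x,y numeric samples, each of length >= 2; at least one with
#'   positive variance.
#' @return List with `t`, `df`, `p`, and per-sample `mean` and `var`.
#' @examples
#' welch_t(c(10, 12, 14), c(11, 15, 19, 21))  # t = -1.8, df ~ 4.37
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) stop("both samples have zero variance")
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       mean = c(x = mean(x), y = mean(y)), var = c(x = vx, y = vy))
}

#' Two-sample F-test for equality of variances
#'
#' `F = var(x) / var(y)` with `(nx - 1, ny - 1)` degrees of freedom and a
#' two-sided p-value `2 min(P(F' <= F), P(F' >= F))`.
#'
#' @param x,y numeric samples, each of length >= 2 with positive variance.
#' @return List with `F`, `df1`, `df2`, `p` and the two variances.
#' @export
variance_f_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  vx <- var(x); vy <- var(y)
  if (vx == 0 || vy == 0) stop("zero variance sample")
  df1 <- length(x) - 1L; df2 <- length(y) - 1L
  F <- vx / vy
  p <- 2 * min(pf(F, df1, df2), pf(F, df1, df2, lower.tail = FALSE))
  p <- min(p, 1)
  list(F = F, df1 = df1, df2 = df2, p = p, var = c(x = vx, y = vy))
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric samples of equal length >= 3, neither constant.
#' @return Sample correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  check_pairs(x, y)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input has no defined correlation")
  sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) * sd(x) * sd(y))
}

#' Williams' test for two dependent correlations with one variable in common
#'
#' Tests whether `r12` and `r13` (e.g. the correlations of two cyst-score
#' methods with the same pulmonary-function value) differ, accounting for
#' the dependence induced by `r23` (the correlation between the two
#' methods). The statistic
#' \deqn{t = (r_{12} - r_{13})
#'   \sqrt{\frac{(n-1)(1+r_{23})}
#'        {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{23})^3}}}
#' with \eqn{|R| = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 + 2 r_{12} r_{13}
#' r_{23}}, \eqn{\bar r = (r_{12}+r_{13})/2}, follows a t distribution
#' with `n - 3` degrees of freedom under the null of equal correlations.
#'
#' @param r12,r13 the two dependent correlations sharing variable 1.
#' @param r23 correlation of variables 2 and 3.
#' @param n sample size (>= 4).
#' @return A `correlation_comparison`: list with `r12`, `r13`, `r23`, `n`,
#'   `t`, `df = n - 3` and two-sided `p`.
#' @examples
#' williams_test(0.5, 0.3, 0.4, 100)  # t ~ 2.07, df 97
#' @export
williams_test <- function(r12, r13, r23, n) {
  for (r in c(r12, r13, r23))
    if (!is.finite(r) || abs(r) >= 1) stop("correlations must lie strictly in (-1, 1)")
  if (n < 4) stop("need n >= 4")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR <= 0) stop("correlation matrix is not positive definite")
  rbar <- (r12 + r13) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3
  t <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  df <- n - 3
  structure(list(r12 = r12, r13 = r13, r23 = r23, n = n,
                 t = t, df = df, p = 2 * pt(-abs(t), df), det_R = detR),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("<correlation_comparison> r12=%.3f vs r13=%.3f (r23=%.3f, n=%d): t=%.3f, df=%d, p=%.4g\n",
              x$r12, x$r13, x$r23, x$n, x$t, x$df, x$p))
  invisible(x)
}

#' Truncate score pairs to a common range
#'
#' Retains the pairs whose pairwise mean `(a+b)/2` lies inside
#' `[lo, hi]`, the device used to compare two sets of paired differences
#' over the same score range. Order-preserving.
#'
#' @inheritParams bland_altman
#' @param lo,hi inclusive bounds on the pair mean, `lo < hi`.
#' @return List with filtered `a`, `b`, logical `kept`, and counts
#'   `n_retained` / `n_removed`.
#' @export
range_truncate <- function(a, b, lo, hi) {
  if (length(a) != length(b)) stop("paired samples differ in length")
  if (!(lo < hi)) stop("need lo < hi")
  m <- (a + b) / 2
  kept <- m >= lo & m <= hi
  list(a = a[kept], b = b[kept], kept = kept,
       n_retained = sum(kept), n_removed = sum(!kept))
}

#' Consistency comparison of two rate-of-change samples
#'
#' Compares two methods' cyst-score rates of change in mean (Welch's t)
#' and variance (two-sample F). A consistent method shows a narrower
#' spread of rates across patients, since score fluctuations between
#' visits inflate the rate variance.
#'
#' @param rates_a,rates_b numeric vectors of per-patient rates (%/year),
#'   each of length >= 3, or data frames from [cohort_rates()].
#' @return List with per-method `summary` (n, mean, sd), `welch` (means)
#'   and `f` (variances).
#' @export
consistency_compare <- function(rates_a, rates_b) {
  if (is.data.frame(rates_a)) rates_a <- rates_a$rate
  if (is.data.frame(rates_b)) rates_b <- rates_b$rate
  if (length(rates_a) < 3L || length(rates_b) < 3L)
    stop("need at least 3 rates per method")
  list(
    summary = data.frame(
      method = c("a", "b"),
      n = c(length(rates_a), length(rates_b)),
      mean = c(mean(rates_a), mean(rates_b)),
      sd = c(sd(rates_a), sd(rates_b))
    ),
    welch = welch_t(rates_a, rates_b),
    f = variance_f_test(rates_a, rates_b)
  )
}
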