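#' Absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects, single-measurement, absolute-agreement
#' intraclass correlation (McGraw-Wong ICC(A,1)), the standard scan-rescan
#' reproducibility measure for k repeated measurements on n subjects:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' from the two-way ANOVA mean squares (rows = subjects, columns =
#' measurements). The 95% confidence interval uses the F-distribution
#' method with Satterthwaite degrees of freedom.
#'
#' @param table n x k numeric matrix or data frame, n >= 2 subjects by
#'   k >= 2 measurements, no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `mean_squares` (rows, columns, error), `n`, `k`, `variant`.
#' @export
icc_agreement <- function(table, conf_level = 0.95) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("rating table must be numeric")
  if (anyNA(x)) stop("rating table must have no missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 measurements")
  gm <- mean(x)
  if (sum((x - gm)^2) == 0)
    stop("degenerate input: zero total variance, ICC undefined")
  rowm <- rowMeans(x); colm <- colMeans(x)
  ssr <- k * sum((rowm - gm)^2)
  ssc <- n * sum((colm - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- max(0, sst - ssr - ssc)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf_level
  if (abs(1 - icc) < 1e-12) {
    ci <- c(icc, icc)                   # perfect agreement: no sampling noise
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, df1 = n - 1, df2 = v)
    fu <- qf(1 - alpha / 2, df1 = v, df2 = n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ci <- c(max(-1, min(lower, icc)), min(1, max(upper, icc)))
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2],
                 mean_squares = c(rows = msr, columns = msc, error = mse),
                 n = n, k = k, conf_level = conf_level,
                 variant = "ICC(A,1) two-way random, absolute agreement"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s\nICC = %.3f (%d%% CI %.3f-%.3f), n = %d subjects, k = %d measurements\n",
              x$variant, x$icc, round(100 * x$conf_level), x$ci_low,
              x$ci_high, x$n, x$k))
  invisible(x)
}

#' Pearson product-moment correlation with two-sided p-value
#'
#' Standard r with the two-sided p from the t-transform on n - 2 degrees of
#' freedom (delegating to [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: one series is constant")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mean and sample standard deviation
#'
#' Summaries are reported as mean +/- SD with the sample (n - 1) SD.
#'
#' @param values numeric vector, length >= 2.
#' @return named numeric vector `c(mean, sd)`.
#' @export
summarize_mean_sd <- function(values) {
  if (length(values) < 2) stop("SD undefined for fewer than 2 values")
  c(mean = mean(values), sd = sd(values))
}
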