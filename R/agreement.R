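#' Pearson product-moment correlation
#'
#' Standard Pearson r with the validation needed for method comparison: at
#' least 3 pairs and nonzero variance in both variables.
#'
#' @param x,y Paired numeric vectors.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("'x' and 'y' must have equal length")
  if (length(x) < 3L) stop_invalid("at least 3 pairs are required")
  if (anyNA(x) || anyNA(y)) stop_invalid("missing values are not allowed")
  if (var(x) == 0 || var(y) == 0)
    stop_invalid("correlation undefined: a variable has zero variance")
  cor(x, y)
}

#' Bland-Altman agreement
#'
#' Differences are oriented as `y - x` (second method minus first). Bias is
#' the mean difference; limits of agreement are bias +/- 1.96 times the SD of
#' the differences (n-1 denominator), the classic formulation without a
#' small-sample t correction.
#'
#' @param x First-method values.
#' @param y Second-method values (same length, >= 2 pairs).
#' @return Named list: `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop_invalid("at least 2 pairs are required")
  if (anyNA(x) || anyNA(y)) stop_invalid("missing values are not allowed")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Single-measure intraclass correlation
#'
#' Shrout-Fleiss single-measure ICCs from the ANOVA mean squares of a
#' subjects x raters matrix:
#' \itemize{
#'   \item `one_way_single` (ICC(1,1)): `(MSB - MSW) / (MSB + (k-1) MSW)`,
#'     with `MSB` the between-subject and `MSW` the within-subject mean
#'     square.
#'   \item `two_way_random_single` (ICC(2,1)):
#'     `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with `MSR`
#'     subject, `MSC` rater and `MSE` residual mean squares from the two-way
#'     decomposition. This form penalizes systematic rater offsets.
#' }
#' Negative estimates are reported as-is, not clipped.
#'
#' @param ratings Numeric matrix, subjects in rows (>= 5), raters in columns
#'   (>= 2), no missing cells.
#' @param model `"one_way_single"` or `"two_way_random_single"`.
#' @return The ICC estimate (<= 1; can be negative).
#' @export
icc_single <- function(ratings, model = c("two_way_random_single", "one_way_single")) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop_invalid("at least 5 subjects are required")
  if (k < 2L) stop_invalid("at least 2 raters are required")
  if (anyNA(ratings)) stop_invalid("missing cells are not allowed")
  gm <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_total <- sum((ratings - gm)^2)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  if (model == "one_way_single") {
    msb <- ss_rows / (n - 1)
    msw <- (ss_total - ss_rows) / (n * (k - 1))
    if (msb == 0 && msw == 0)
      stop_invalid("ICC undefined: ratings have no variance at all")
    (msb - msw) / (msb + (k - 1) * msw)
  } else {
    msr <- ss_rows / (n - 1)
    msc <- ss_cols / (k - 1)
    mse <- (ss_total - ss_rows - ss_cols) / ((n - 1) * (k - 1))
    denom <- msr + (k - 1) * mse + k * (msc - mse) / n
    if (denom == 0)
      stop_invalid("ICC undefined: ratings have no variance at all")
    (msr - mse) / denom
  }
}

#' Method-agreement report
#'
#' Combines Pearson correlation, Bland-Altman bias and limits of agreement,
#' and a single-measure ICC for one pair of methods measuring the same
#' quantity. Differences are oriented `y - x` (second method minus first).
#'
#' @param x First-method values (>= 3 pairs).
#' @param y Second-method values.
#' @param icc_model ICC form, see [icc_single()].
#' @param label Optional label for printing (e.g. `"EOA: Doppler vs PC"`).
#' @return Object of class `agreement_report`: list with `n`, `pearson_r`,
#'   `bias`, `loa_low`, `loa_high`, `icc`, `icc_model`, `label`, and the
#'   paired data.
#' @export
agreement <- function(x, y, icc_model = "two_way_random_single", label = NULL) {
  r <- pearson(x, y)
  ba <- bland_altman(x, y)
  icc <- if (length(x) >= 5L) icc_single(cbind(x, y), icc_model) else NA_real_
  structure(list(n = length(x), pearson_r = r,
                 bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                 sd_diff = ba$sd_diff, icc = icc, icc_model = icc_model,
                 label = label %||% "method B vs method A",
                 x = x, y = y),
            class = "agreement_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement: %s (differences = second - first, n = %d)\n",
              x$label, x$n))
  cat(sprintf("  Pearson r : %.3f\n", x$pearson_r))
  cat(sprintf("  bias      : %.3f  (LoA %.3f to %.3f)\n",
              x$bias, x$loa_low, x$loa_high))
  if (is.finite(x$icc))
    cat(sprintf("  ICC       : %.3f  (%s)\n", x$icc, x$icc_model))
  invisible(x)
}

#' Bland-Altman plot of an agreement report
#'
#' Mean of the pair on the x axis, difference (second minus first) on the y
#' axis, with bias and limits of agreement as horizontal lines.
#'
#' @param x An `agreement_report`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.agreement_report <- function(x, ...) {
  m <- (x$x + x$y) / 2
  d <- x$y - x$x
  graphics::plot(m, d, xlab = "mean of methods", ylab = "difference (B - A)",
                 main = x$label, ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  invisible(x)
}
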