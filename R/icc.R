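#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single rater
#'
#' Computes the single-rater absolute-agreement ICC from the two-way ANOVA
#' decomposition of a cases-by-raters grid (rows = cases treated as random,
#' columns = raters treated as random):
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the mean squares for rows
#' (cases), columns (raters) and error, n the number of cases and k the
#' number of raters. The confidence interval uses the F-distribution based
#' formulas for this ICC form (McGraw & Wong case 2A with a
#' Satterthwaite-approximated denominator degrees of freedom).
#'
#' Categorical ratings are accepted: ordered categories are encoded as
#' consecutive integers 0, 1, 2, ... in label-set order before the ANOVA,
#' so an ICC can be reported for category-valued as well as raw-percentage
#' data.
#'
#' @param x numeric matrix (cases x raters), a `percent_ratings` or a
#'   `categorical_ratings` object.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return object of class `icc_result`: `estimate`, `ci_low`, `ci_high`,
#'   `ms_rows`, `ms_cols`, `ms_error`, `n_cases`, `n_raters`,
#'   `conf_level`, `reliability`.
#' @examples
#' set.seed(1)
#' g <- matrix(rnorm(40, rep(1:10, 4), 0.5), ncol = 4)
#' icc_2_1(g)
#' @export
icc_2_1 <- function(x, conf_level = 0.95) {
  if (inherits(x, "categorical_ratings")) {
    x <- matrix(match(as.vector(unclass_ratings(x)), attr(x, "label_set")) - 1,
                nrow = nrow(x))
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 cases and 2 raters", call. = FALSE)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * max(1, abs(grand))^2)
    stop("ICC undefined: no between-case variance", call. = FALSE)
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    ci <- c(est, est)  # fully degenerate: identical raters
  } else {
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lo, hi)
  }
  out <- structure(list(estimate = est, ci_low = ci[1], ci_high = ci[2],
                        ms_rows = msr, ms_cols = msc, ms_error = mse,
                        n_cases = n, n_raters = k, conf_level = conf_level),
                   class = "icc_result")
  out$reliability <- grade_reliability(out)
  out
}

#' @export
print.icc_result <- function(x, digits = 3, ...) {
  cat(sprintf("ICC(2,1) = %.*f, %d%% CI (%.*f, %.*f) - %s\n",
              digits, x$estimate, round(100 * x$conf_level),
              digits, x$ci_low, digits, x$ci_high, x$reliability))
  cat(sprintf("  %d cases x %d raters; MS rows %.4g, cols %.4g, error %.4g\n",
              x$n_cases, x$n_raters, x$ms_rows, x$ms_cols, x$ms_error))
  invisible(x)
}

#' Reliability grading of an ICC with its confidence interval
#'
#' Bands follow the usual convention: poor (<= 0.5), moderate
#' (0.5–0.75), good (0.75–0.9), excellent (> 0.9). The confidence
#' interval is taken into account: when its two bounds fall into
#' different bands the label straddles them (e.g. "good to excellent"
#' for an estimate of 0.92 with CI 0.88–0.95).
#'
#' @param icc an `icc_result`, or a numeric estimate (then `ci_low` and
#'   `ci_high` must be given).
#' @param ci_low,ci_high confidence bounds when `icc` is numeric.
#' @return a reliability label string.
#' @export
grade_reliability <- function(icc, ci_low = NULL, ci_high = NULL) {
  if (inherits(icc, "icc_result")) {
    ci_low <- icc$ci_low; ci_high <- icc$ci_high; icc <- icc$estimate
  }
  band <- function(v) {
    if (v > 0.9) "excellent"
    else if (v > 0.75) "good"
    else if (v > 0.5) "moderate"
    else "poor"
  }
  lo <- band(ci_low); hi <- band(ci_high)
  if (lo == hi) band(icc) else paste(lo, "to", hi)
}
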