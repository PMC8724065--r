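#' Kruskal-Wallis rank test on groups of values
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation for the
#' p value (via [stats::kruskal.test()]). The fully tied case — all values
#' identical across all groups — is returned as H = 0, p = 1 rather than an
#' error: with no rank variation there is no evidence of any difference.
#'
#' @param groups list of two or more numeric vectors, each non-empty.
#' @return object of class `kw_result`: `h_statistic`, `df`, `p_value`,
#'   group sizes.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
#' kruskal_wallis(list(c(1, 1), c(1, 1)))  # H = 0, p = 1
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of >= 2 groups", call. = FALSE)
  if (any(!vapply(groups, length, 1L)))
    stop("every group needs >= 1 value", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values)) stop("missing values are not allowed", call. = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  df <- length(groups) - 1L
  if (length(unique(values)) == 1L) {
    res <- list(h_statistic = 0, df = df, p_value = 1)
  } else {
    kt <- stats::kruskal.test(values, g)
    res <- list(h_statistic = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value)
  }
  structure(c(res, list(group_sizes = vapply(groups, length, 1L))),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, digits = 4, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.*g, df = %d, p = %.*g\n",
              digits, x$h_statistic, x$df, digits, x$p_value))
  invisible(x)
}

#' Compare the minimum OPA curves of two ONEST analyses
#'
#' Applies the Kruskal-Wallis test to the two minimum-envelope value
#' sequences (the k = 2..N points treated as observations). Note that the
#' points of one curve are statistically dependent — each is a prefix of
#' the next — so the p value is a descriptive comparison of curve levels,
#' not an exact test; this mirrors how minimum OPA curves are conventionally
#' compared.
#'
#' @param result_a,result_b `onest_result` objects from panels of equal N.
#' @return a `kw_result` with the two curves attached as `curve_a`,
#'   `curve_b`.
#' @export
compare_min_curves <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "onest_result"),
            inherits(result_b, "onest_result"))
  if (result_a$n_observers != result_b$n_observers)
    stop("panels have different numbers of observers (",
         result_a$n_observers, " vs ", result_b$n_observers, ")",
         call. = FALSE)
  out <- kruskal_wallis(list(result_a$min_curve, result_b$min_curve))
  out$curve_a <- result_a$min_curve
  out$curve_b <- result_b$min_curve
  out
}

#' Sampled versus exhaustive minimum OPA curves
#'
#' Runs a sampled ONEST analysis and the exhaustive subset-enumeration
#' envelope on the same matrix and compares their minimum curves with
#' Kruskal-Wallis — the check that a moderate number of random orderings
#' already pins down the worst-case agreement curve.
#'
#' @param x a `categorical_ratings` matrix (within the exhaustive guard).
#' @param n_perm,seed passed to [onest()].
#' @return a `kw_result` with `curve_a` (sampled min) and `curve_b`
#'   (exhaustive min) attached.
#' @export
compare_sampled_vs_exhaustive <- function(x, n_perm = 100, seed = NULL) {
  res <- onest(x, n_perm = n_perm, seed = seed)
  env <- exhaustive_envelope(x)
  out <- kruskal_wallis(list(res$min_curve, env$min_curve))
  out$curve_a <- res$min_curve
  out$curve_b <- env$min_curve
  out
}
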