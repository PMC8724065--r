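#' Categorization schemes for staining percentages
#'
#' A categorization scheme maps a staining percentage in \[0, 100\] to an
#' ordered category label through a list of bins that partition \[0, 100\]
#' with no gaps or overlaps. Built-in schemes cover the common breast-marker
#' cut-offs:
#'
#' * `er3`, `pr3`, `ki67_3cat` — negative (< 1%), low positive (1–10%,
#'   both boundaries included), positive (> 10%).
#' * `stgallen2009` — Ki67 low (<= 15%), intermediate (16–30%), high (> 30%).
#' * `stgallen2011` — low (<= 13%), high (> 13%).
#' * `stgallen2013` — low (<= 20%), high (> 20%).
#' * `stgallen2015` — relative to the median Ki67 labelling `m` of ER+
#'   cases (parameter, default 15%): low at or below `m - 10`, high at or
#'   above `m + 10`, intermediate strictly between.
#'
#' @param name scheme identifier.
#' @param lower,upper numeric vectors of bin bounds.
#' @param lower_inc,upper_inc logical vectors: is each bound included?
#' @param labels character vector of unique bin labels, in increasing order
#'   of the quantity binned.
#' @param parameters optional named list of scheme parameters (e.g. the
#'   St Gallen 2015 median).
#' @return an object of class `categorization_scheme`.
#' @examples
#' categorize(percent_ratings(matrix(c(0, 5, 95, 0, 10, 90), ncol = 2)),
#'            scheme("er3"))
#' @export
categorization_scheme <- function(name, lower, upper, lower_inc, upper_inc,
                                  labels, parameters = list()) {
  nb <- length(labels)
  stopifnot(length(lower) == nb, length(upper) == nb,
            length(lower_inc) == nb, length(upper_inc) == nb)
  if (anyDuplicated(labels)) stop("bin labels must be unique", call. = FALSE)
  ord <- order(lower)
  lower <- lower[ord]; upper <- upper[ord]
  lower_inc <- lower_inc[ord]; upper_inc <- upper_inc[ord]
  labels <- labels[ord]
  if (any(upper < lower)) stop("bin with upper < lower", call. = FALSE)
  if (!(lower[1] == 0 && lower_inc[1]) || !(upper[nb] == 100 && upper_inc[nb]))
    stop("bins must span [0, 100] inclusively", call. = FALSE)
  if (nb > 1) {
    joins <- upper[-nb] == lower[-1] & xor(upper_inc[-nb], lower_inc[-1])
    if (!all(joins))
      stop("bins must partition [0, 100] with no gaps or overlaps", call. = FALSE)
  }
  structure(list(name = name, lower = lower, upper = upper,
                 lower_inc = lower_inc, upper_inc = upper_inc,
                 labels = labels, parameters = parameters),
            class = "categorization_scheme")
}

#' @rdname categorization_scheme
#' @param ... scheme parameters passed to the builder (currently only
#'   `median` for `stgallen2015`).
#' @export
scheme <- function(name, ...) {
  params <- list(...)
  three_cat <- function(nm) categorization_scheme(
    nm,
    lower = c(0, 1, 10), upper = c(1, 10, 100),
    lower_inc = c(TRUE, TRUE, FALSE), upper_inc = c(FALSE, TRUE, TRUE),
    labels = c("negative", "low_positive", "positive"))
  switch(name,
    er3 = three_cat("er3"),
    pr3 = three_cat("pr3"),
    ki67_3cat = three_cat("ki67_3cat"),
    stgallen2009 = categorization_scheme(
      "stgallen2009",
      lower = c(0, 15, 30), upper = c(15, 30, 100),
      lower_inc = c(TRUE, FALSE, FALSE), upper_inc = c(TRUE, TRUE, TRUE),
      labels = c("low", "intermediate", "high")),
    stgallen2011 = categorization_scheme(
      "stgallen2011",
      lower = c(0, 13), upper = c(13, 100),
      lower_inc = c(TRUE, FALSE), upper_inc = c(TRUE, TRUE),
      labels = c("low", "high")),
    stgallen2013 = categorization_scheme(
      "stgallen2013",
      lower = c(0, 20), upper = c(20, 100),
      lower_inc = c(TRUE, FALSE), upper_inc = c(TRUE, TRUE),
      labels = c("low", "high")),
    stgallen2015 = {
      m <- if (is.null(params$median)) 15 else params$median
      if (!is.numeric(m) || m - 10 < 0 || m + 10 > 100)
        stop("stgallen2015 median must satisfy 10 <= median <= 90", call. = FALSE)
      categorization_scheme(
        "stgallen2015",
        lower = c(0, m - 10, m + 10), upper = c(m - 10, m + 10, 100),
        lower_inc = c(TRUE, FALSE, TRUE), upper_inc = c(TRUE, FALSE, TRUE),
        labels = c("low", "intermediate", "high"),
        parameters = list(median = m))
    },
    stop("unknown scheme: ", name, call. = FALSE)
  )
}

#' @export
print.categorization_scheme <- function(x, ...) {
  cat("categorization scheme '", x$name, "'\n", sep = "")
  br <- function(inc, open, close) ifelse(inc, close, open)
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %s%g, %g%s -> %s\n",
                ifelse(x$lower_inc[i], "[", "("), x$lower[i], x$upper[i],
                ifelse(x$upper_inc[i], "]", ")"), x$labels[i]))
  }
  invisible(x)
}

#' Apply a categorization scheme to percentage values
#'
#' Maps every element of a percent rating matrix (or a bare numeric vector)
#' to its bin label. The output label set equals the scheme's labels in
#' scheme order, so downstream ordinal encodings are stable even when some
#' category is absent from the data.
#'
#' @param x a `percent_ratings` matrix or numeric vector in \[0, 100\].
#' @param scheme a `categorization_scheme`.
#' @return a `categorical_ratings` matrix (or character vector for vector
#'   input).
#' @export
categorize <- function(x, scheme) {
  stopifnot(inherits(scheme, "categorization_scheme"))
  v <- if (inherits(x, "rating_matrix")) as.vector(unclass_ratings(x)) else as.numeric(x)
  if (anyNA(v) || any(v < 0 | v > 100))
    stop("values must be in [0, 100]", call. = FALSE)
  idx <- rep.int(NA_integer_, length(v))
  for (i in seq_along(scheme$labels)) {
    lo <- scheme$lower[i]; hi <- scheme$upper[i]
    in_bin <- (v > lo | (scheme$lower_inc[i] & v == lo)) &
              (v < hi | (scheme$upper_inc[i] & v == hi))
    idx[in_bin] <- i
  }
  if (anyNA(idx))
    stop("value falls in no bin of scheme '", scheme$name, "': ",
         v[which(is.na(idx))[1]], call. = FALSE)
  lab <- scheme$labels[idx]
  if (!inherits(x, "rating_matrix")) return(lab)
  categorical_ratings(matrix(lab, nrow = nrow(x), ncol = ncol(x)),
                      label_set = scheme$labels,
                      case_ids = rownames(x), observer_ids = colnames(x))
}
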