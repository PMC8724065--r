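#' Rating matrices: cases by observers
#'
#' A rating matrix holds one score per case and observer. Two kinds are
#' supported: raw staining percentages in \[0, 100\]
#' (`percent_ratings`) and categorical labels from a finite ordered label
#' set (`categorical_ratings`). Rows are cases, columns are observers.
#'
#' @param values numeric matrix (cases x observers) of percentages in
#'   \[0, 100\].
#' @param case_ids character vector of unique case identifiers; defaults to
#'   the matrix rownames or `case_1 ... case_n`.
#' @param observer_ids character vector of unique observer identifiers;
#'   defaults to the matrix colnames or `obs_1 ... obs_N`.
#' @return An object of class `percent_ratings` or `categorical_ratings`:
#'   a matrix with `case_ids`/`observer_ids` as dimnames (and, for the
#'   categorical kind, a `label_set` attribute giving the ordered levels).
#' @examples
#' m <- percent_ratings(matrix(c(0, 5, 100, 0, 10, 95), ncol = 2))
#' n_cases(m)
#' @export
percent_ratings <- function(values, case_ids = NULL, observer_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  ids <- resolve_ids(values, case_ids, observer_ids)
  dimnames(values) <- ids
  validate_rating_shape(values)
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("missing or non-finite rating for case '", rownames(values)[bad[1]],
         "', observer '", colnames(values)[bad[2]], "'", call. = FALSE)
  }
  if (any(values < 0 | values > 100)) {
    bad <- which(values < 0 | values > 100, arr.ind = TRUE)[1, ]
    stop("rating out of [0, 100] for case '", rownames(values)[bad[1]],
         "', observer '", colnames(values)[bad[2]], "': ",
         values[bad[1], bad[2]], call. = FALSE)
  }
  structure(values, class = c("percent_ratings", "rating_matrix", "matrix"))
}

#' @rdname percent_ratings
#' @param labels character matrix (cases x observers) of category labels.
#' @param label_set ordered character vector of permitted labels; defaults to
#'   the sorted unique labels present.
#' @export
categorical_ratings <- function(labels, label_set = NULL,
                                case_ids = NULL, observer_ids = NULL) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "character"
  ids <- resolve_ids(labels, case_ids, observer_ids)
  dimnames(labels) <- ids
  validate_rating_shape(labels)
  if (anyNA(labels)) {
    bad <- which(is.na(labels), arr.ind = TRUE)[1, ]
    stop("missing label for case '", rownames(labels)[bad[1]],
         "', observer '", colnames(labels)[bad[2]], "'", call. = FALSE)
  }
  if (is.null(label_set)) label_set <- sort(unique(as.vector(labels)))
  label_set <- as.character(label_set)
  if (anyDuplicated(label_set)) stop("label_set has duplicates", call. = FALSE)
  unknown <- setdiff(unique(as.vector(labels)), label_set)
  if (length(unknown)) {
    stop("labels not in label_set: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(labels, label_set = label_set,
            class = c("categorical_ratings", "rating_matrix", "matrix"))
}

resolve_ids <- function(x, case_ids, observer_ids) {
  if (is.null(case_ids)) {
    case_ids <- rownames(x)
    if (is.null(case_ids)) case_ids <- paste0("case_", seq_len(nrow(x)))
  }
  if (is.null(observer_ids)) {
    observer_ids <- colnames(x)
    if (is.null(observer_ids)) observer_ids <- paste0("obs_", seq_len(ncol(x)))
  }
  list(as.character(case_ids), as.character(observer_ids))
}

validate_rating_shape <- function(x) {
  if (nrow(x) < 1) stop("need at least 1 case", call. = FALSE)
  if (ncol(x) < 2) stop("need at least 2 observers", call. = FALSE)
  if (anyDuplicated(rownames(x))) stop("duplicate case ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate observer ids", call. = FALSE)
  invisible(x)
}

#' @rdname percent_ratings
#' @param x a rating matrix.
#' @export
n_cases <- function(x) nrow(x)

#' @rdname percent_ratings
#' @export
n_observers <- function(x) ncol(x)

#' @rdname percent_ratings
#' @export
label_set <- function(x) attr(x, "label_set")

#' @export
print.rating_matrix <- function(x, ...) {
  kind <- if (inherits(x, "percent_ratings")) "percent" else "categorical"
  cat(sprintf("%s rating matrix: %d cases x %d observers\n",
              kind, nrow(x), ncol(x)))
  if (kind == "categorical") {
    cat("labels:", paste(attr(x, "label_set"), collapse = " < "), "\n")
  }
  print(utils::head(unclass_ratings(x), 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more cases)\n", sep = "")
  invisible(x)
}

unclass_ratings <- function(x) {
  attr(x, "label_set") <- NULL
  class(x) <- "matrix"
  x
}

#' Read and write rating matrices as CSV
#'
#' The CSV dialect is fixed: comma-separated, UTF-8, decimal point, a
#' mandatory header row of observer identifiers and a first column of case
#' identifiers. Missing cells are a hard error by default because OPA is
#' undefined for partially rated cases; `drop_incomplete = TRUE` removes
#' such cases listwise with a warning stating how many were dropped.
#'
#' @param path file path.
#' @param value_kind `"percent"` for numeric percentages in \[0, 100\],
#'   `"categorical"` for labels.
#' @param label_set for categorical input, the ordered label set (default:
#'   sorted unique labels found in the file).
#' @param drop_incomplete drop cases with any missing cell instead of
#'   raising an error.
#' @return a `percent_ratings` or `categorical_ratings` object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_ratings(percent_ratings(matrix(c(0, 5, 100, 0, 10, 95), ncol = 2)), f)
#' read_ratings(f)
#' @export
read_ratings <- function(path, value_kind = c("percent", "categorical"),
                         label_set = NULL, drop_incomplete = FALSE) {
  value_kind <- match.arg(value_kind)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(raw) < 3) stop("expected a case-id column plus >= 2 observer columns",
                          call. = FALSE)
  case_ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  body[!nzchar(trimws(body))] <- NA
  incomplete <- apply(body, 1, anyNA)
  if (any(incomplete)) {
    if (drop_incomplete) {
      warning(sum(incomplete), " case(s) with missing ratings dropped listwise",
              call. = FALSE)
      body <- body[!incomplete, , drop = FALSE]
      case_ids <- case_ids[!incomplete]
      if (nrow(body) == 0) stop("no complete cases left", call. = FALSE)
    } else {
      i <- which(incomplete)[1]
      j <- which(is.na(body[i, ]))[1]
      stop("missing rating for case '", case_ids[i], "', observer '",
           colnames(body)[j], "' (use drop_incomplete = TRUE for listwise deletion)",
           call. = FALSE)
    }
  }
  if (value_kind == "percent") {
    num <- suppressWarnings(array(as.numeric(body), dim = dim(body),
                                  dimnames = dimnames(body)))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1, ]
      stop("non-numeric rating for case '", case_ids[bad[1]], "', observer '",
           colnames(body)[bad[2]], "': ", body[bad[1], bad[2]], call. = FALSE)
    }
    percent_ratings(num, case_ids = case_ids)
  } else {
    categorical_ratings(body, label_set = label_set, case_ids = case_ids)
  }
}

#' @rdname read_ratings
#' @param x a rating matrix to write.
#' @export
write_ratings <- function(x, path) {
  stopifnot(inherits(x, "rating_matrix"))
  df <- data.frame(case = rownames(x), unclass_ratings(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
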