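#' Allred (quick) score for ER/PR immunohistochemistry
#'
#' The Allred quick score is the sum of an intensity subscore (0 = nil,
#' 1 = weak, 2 = medium, 3 = strong) and a proportion-of-positive-cells
#' subscore (0–5). The proportion subscore uses the standard published
#' bins, with the 1% and 10% boundaries aligned to the usual ER/PR
#' reporting convention: 0 for 0%, 1 for (0, 1)%, 2 for \[1, 10\]%,
#' 3 for (10, 33\]%, 4 for (33, 66\]%, 5 for (66, 100\]%. A quick score of
#' 1 is impossible: intensity 0 and proportion 0 imply each other.
#'
#' @param intensity integer intensity subscore in 0–3 (non-integer
#'   "average intensity" values are rejected).
#' @param percent_positive percentage of positive cells in \[0, 100\].
#' @return a list of class `allred_score` with `intensity_subscore`,
#'   `proportion_subscore` and `quick_score`; vector inputs give vector
#'   fields.
#' @examples
#' allred_from_components(3, 95)$quick_score  # 8
#' allred_from_components(2, 5)$quick_score   # 4
#' @export
allred_from_components <- function(intensity, percent_positive) {
  if (length(intensity) != length(percent_positive))
    stop("intensity and percent_positive lengths differ", call. = FALSE)
  if (anyNA(intensity) || any(intensity != as.integer(intensity)) ||
      any(intensity < 0 | intensity > 3))
    stop("intensity subscore must be an integer in 0..3", call. = FALSE)
  if (anyNA(percent_positive) || any(percent_positive < 0 | percent_positive > 100))
    stop("percent_positive must be in [0, 100]", call. = FALSE)
  mismatch <- xor(intensity == 0, percent_positive == 0)
  if (any(mismatch))
    stop("inconsistent components: intensity 0 requires 0% positive cells ",
         "and vice versa", call. = FALSE)
  prop <- allred_proportion_subscore(percent_positive)
  structure(list(intensity_subscore = as.integer(intensity),
                 proportion_subscore = prop,
                 quick_score = as.integer(intensity) + prop),
            class = "allred_score")
}

allred_proportion_subscore <- function(p) {
  s <- integer(length(p))
  s[p > 0 & p < 1] <- 1L
  s[p >= 1 & p <= 10] <- 2L
  s[p > 10 & p <= 33] <- 3L
  s[p > 33 & p <= 66] <- 4L
  s[p > 66] <- 5L
  s
}

#' Group Allred quick scores into four reporting categories
#'
#' Collapses quick scores into the broader groups used in breast-screening
#' pathology practice: 0 and 2; 3–4; 5–6; 7–8.
#'
#' @param quick_score integer vector of quick scores in \{0, 2, ..., 8\}.
#' @return character vector of group labels (`"0,2"`, `"3-4"`, `"5-6"`,
#'   `"7-8"`), ordered factor-compatible via [allred_group_labels()].
#' @examples
#' group_allred(c(0, 2, 4, 7))
#' @export
group_allred <- function(quick_score) {
  if (anyNA(quick_score) || any(quick_score != as.integer(quick_score)))
    stop("quick_score must be integer", call. = FALSE)
  if (any(quick_score == 1 | quick_score < 0 | quick_score > 8))
    stop("quick_score must be in {0, 2, ..., 8} (1 is impossible)", call. = FALSE)
  lab <- character(length(quick_score))
  lab[quick_score <= 2] <- "0,2"
  lab[quick_score %in% c(3, 4)] <- "3-4"
  lab[quick_score %in% c(5, 6)] <- "5-6"
  lab[quick_score >= 7] <- "7-8"
  lab
}

#' @rdname group_allred
#' @export
allred_group_labels <- function() c("0,2", "3-4", "5-6", "7-8")

#' Categorical ratings from Allred quick scores or intensity scores
#'
#' `allred_ratings` maps a matrix of quick scores to the four-group
#' categorization; `intensity_ratings` validates integer intensity scores
#' 0–3 and returns them as an ordered categorical matrix. Both are the
#' scheme-like entry points for score-valued (rather than percentage-
#' valued) data.
#'
#' @param x numeric matrix or `percent_ratings`-like matrix of scores
#'   (cases x observers).
#' @return a `categorical_ratings` matrix.
#' @export
allred_ratings <- function(x) {
  v <- as.matrix(x)
  lab <- matrix(group_allred(as.vector(v)), nrow = nrow(v))
  categorical_ratings(lab, label_set = allred_group_labels(),
                      case_ids = rownames(v), observer_ids = colnames(v))
}

#' @rdname allred_ratings
#' @export
intensity_ratings <- function(x) {
  v <- as.matrix(x)
  if (anyNA(v) || any(v != as.integer(v)) || any(v < 0 | v > 3))
    stop("intensity scores must be integers in 0..3", call. = FALSE)
  categorical_ratings(matrix(as.character(as.integer(v)), nrow = nrow(v)),
                      label_set = c("0", "1", "2", "3"),
                      case_ids = rownames(v), observer_ids = colnames(v))
}
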