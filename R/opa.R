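#' Overall percent agreement (OPA)
#'
#' The OPA of a set of observers is the proportion of cases on which every
#' observer in the set assigns the identical category label.
#'
#' @param x a `categorical_ratings` matrix.
#' @param observers integer indices (or observer ids) of the observers to
#'   include; at least 2. Default: all observers.
#' @return a proportion in \[0, 1\].
#' @examples
#' m <- categorical_ratings(rbind(c("A","A","A"), c("A","A","B"),
#'                                c("B","B","B"), c("A","B","B")))
#' compute_opa(m)          # 0.5
#' compute_opa(m, c(1, 2)) # 0.75
#' @export
compute_opa <- function(x, observers = seq_len(ncol(x))) {
  stopifnot(inherits(x, "categorical_ratings"))
  observers <- resolve_observers(x, observers)
  if (length(observers) < 2)
    stop("OPA needs at least 2 observers", call. = FALSE)
  sub <- unclass_ratings(x)[, observers, drop = FALSE]
  mean(rowSums(sub == sub[, 1]) == ncol(sub))
}

resolve_observers <- function(x, observers) {
  if (is.character(observers)) observers <- match(observers, colnames(x))
  observers <- as.integer(observers)
  if (anyNA(observers) || any(observers < 1 | observers > ncol(x)))
    stop("observer index out of range", call. = FALSE)
  if (anyDuplicated(observers)) stop("duplicate observer index", call. = FALSE)
  observers
}

#' OPA curve (OPAC) along one ordering of observers
#'
#' For an ordering of all N observers, the OPA curve is the sequence of OPA
#' values of its first k observers, k = 2..N. Because adding an observer can
#' only shrink the set of fully agreed cases, every OPAC is non-increasing.
#'
#' @param x a `categorical_ratings` matrix.
#' @param perm an ordering of all observer indices `1..N`.
#' @return numeric vector of length N - 1 named by k = 2..N.
#' @export
opac <- function(x, perm) {
  stopifnot(inherits(x, "categorical_ratings"))
  N <- ncol(x)
  perm <- as.integer(perm)
  if (length(perm) != N || !setequal(perm, seq_len(N)))
    stop("perm must be a permutation of 1..", N, call. = FALSE)
  opac_codes(code_matrix(x), perm)
}

code_matrix <- function(x) {
  m <- matrix(match(as.vector(unclass_ratings(x)), attr(x, "label_set")),
              nrow = nrow(x))
  m
}

# OPAC from a precomputed integer code matrix; incremental prefix scan.
opac_codes <- function(codes, perm) {
  N <- ncol(codes)
  agree <- rep.int(TRUE, nrow(codes))
  ref <- codes[, perm[1]]
  out <- numeric(N - 1)
  for (k in 2:N) {
    agree <- agree & (codes[, perm[k]] == ref)
    out[k - 1] <- mean(agree)
  }
  names(out) <- paste0("k", 2:N)
  out
}

#' Count and sample observer permutations
#'
#' `count_permutations` returns N!. `sample_permutations` draws `n_perm`
#' distinct orderings uniformly without replacement; when `n_perm >= N!`
#' every ordering is returned once, in a deterministic (lexicographic)
#' order, so results become seed-independent.
#'
#' @param n_observers number of observers N.
#' @param n_perm number of orderings requested.
#' @param seed integer seed for reproducible sampling (`NULL` uses the
#'   current RNG state).
#' @return `count_permutations`: a number. `sample_permutations`: a matrix
#'   with one ordering per row.
#' @examples
#' count_permutations(9)  # 362880
#' nrow(sample_permutations(3, 10))  # 6: all of 3!
#' @export
count_permutations <- function(n_observers) {
  stopifnot(n_observers >= 1)
  factorial(n_observers)
}

#' @rdname count_permutations
#' @export
sample_permutations <- function(n_observers, n_perm, seed = NULL) {
  stopifnot(n_observers >= 2, n_perm >= 1)
  total <- count_permutations(n_observers)
  if (n_perm >= total) return(all_permutations(n_observers))
  draw <- function() {
    if (total <= 40320) {
      # small N: enumerate once and subsample rows
      all <- all_permutations(n_observers)
      all[sort(sample.int(nrow(all), n_perm)), , drop = FALSE]
    } else {
      # large N: rejection-sample; collisions are vanishingly rare but
      # are removed to guarantee distinctness
      seen <- character(0)
      out <- matrix(0L, nrow = n_perm, ncol = n_observers)
      got <- 0L
      while (got < n_perm) {
        p <- sample.int(n_observers)
        key <- paste(p, collapse = ",")
        if (!key %in% seen) {
          got <- got + 1L
          seen <- c(seen, key)
          out[got, ] <- p
        }
      }
      out
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# all N! orderings in lexicographic order, one per row
all_permutations <- function(n) {
  if (n > 10) stop("refusing to enumerate ", n, "! orderings; sample instead",
                   call. = FALSE)
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1)
  blocks <- lapply(seq_len(n), function(first) {
    rest <- seq_len(n)[-first]
    cbind(first, matrix(rest[sub], nrow = nrow(sub)))
  })
  out <- do.call(rbind, blocks)
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Plateau of an OPA curve
#'
#' The plateau is the smallest observer count k at which the curve is
#' within `eps` of its terminal value OPA(N); its OPA estimates the
#' agreement a full panel would achieve.
#'
#' @param curve numeric OPA curve indexed k = 2..N (as returned by [opac()]
#'   or an envelope from [onest()]).
#' @param eps non-negative tolerance on the gap to the terminal value.
#' @return list with `plateau_k` and `plateau_value`.
#' @export
detect_plateau <- function(curve, eps = 0.02) {
  stopifnot(is.numeric(curve), length(curve) >= 1, eps >= 0)
  gap <- unname(curve - curve[length(curve)])
  k <- which(gap <= eps)[1] + 1L
  list(plateau_k = k, plateau_value = unname(curve[k - 1L]))
}

#' ONEST analysis of a categorical rating matrix
#'
#' Draws `n_perm` distinct observer orderings, computes their OPA curves,
#' and summarizes them: pointwise minimum / maximum / mean envelopes over
#' k = 2..N, the bandwidth (difference between the best and worst
#' two-observer OPA), the plateau of the mean envelope, the OPA of the full
#' panel, and per-category unanimous case counts.
#'
#' By default the bandwidth is computed exactly over all `choose(N, 2)`
#' observer pairs — the extreme two-observer agreement — rather than over
#' the sampled curves only; set `bandwidth = "sampled"` for the
#' envelope-based variant. The min/max envelopes are pointwise extremes and
#' need not be realized by any single ordering; `min_realized` reports
#' whether some sampled curve attains the minimum envelope at every k.
#'
#' @param x a `categorical_ratings` matrix.
#' @param n_perm number of orderings to sample (100 by default; values
#'   `>= N!` switch to exhaustive enumeration and make the result
#'   seed-independent).
#' @param seed integer seed for the permutation sample.
#' @param plateau_eps tolerance for [detect_plateau()].
#' @param plateau_on envelope on which the plateau is detected.
#' @param bandwidth `"exact"` (all pairs) or `"sampled"` (envelope at k = 2).
#' @return an object of class `onest_result`; see Details.
#' @seealso [exhaustive_envelope()], [plot.onest_result()]
#' @export
onest <- function(x, n_perm = 100, seed = NULL, plateau_eps = 0.02,
                  plateau_on = c("mean", "min"),
                  bandwidth = c("exact", "sampled")) {
  stopifnot(inherits(x, "categorical_ratings"), n_perm >= 1)
  plateau_on <- match.arg(plateau_on)
  bandwidth <- match.arg(bandwidth)
  N <- ncol(x)
  codes <- code_matrix(x)
  perms <- sample_permutations(N, n_perm, seed = seed)
  exhaustive <- nrow(perms) == count_permutations(N)
  curves <- do.call(rbind, lapply(seq_len(nrow(perms)),
                                  function(i) opac_codes(codes, perms[i, ])))
  colnames(curves) <- paste0("k", 2:N)
  min_curve <- apply(curves, 2, min)
  max_curve <- apply(curves, 2, max)
  mean_curve <- colMeans(curves)
  pair_opa <- utils::combn(N, 2, function(s) {
    mean(codes[, s[1]] == codes[, s[2]])
  })
  bw <- if (bandwidth == "exact") max(pair_opa) - min(pair_opa)
        else unname(max_curve[1] - min_curve[1])
  pl_curve <- if (plateau_on == "mean") mean_curve else min_curve
  pl <- detect_plateau(pl_curve, plateau_eps)
  min_realized <- any(apply(curves, 1, function(cv) all(cv == min_curve)))
  structure(list(
    k = 2:N, n_observers = N, n_cases = nrow(x),
    curves = curves, permutations = perms,
    min_curve = min_curve, max_curve = max_curve, mean_curve = mean_curve,
    bandwidth = bw, bandwidth_mode = bandwidth,
    pair_opa_min = min(pair_opa), pair_opa_max = max(pair_opa),
    plateau_k = pl$plateau_k, plateau_value = pl$plateau_value,
    plateau_eps = plateau_eps, plateau_on = plateau_on,
    opa_all = unname(mean_curve[N - 1]),
    consensus = category_consensus_counts(x),
    n_perm = nrow(perms), seed = seed, exhaustive = exhaustive,
    min_realized = min_realized), class = "onest_result")
}

#' @export
print.onest_result <- function(x, digits = 3, ...) {
  cat(sprintf("ONEST: %d cases, %d observers, %d ordering(s)%s\n",
              x$n_cases, x$n_observers, x$n_perm,
              if (x$exhaustive) " (exhaustive)" else ""))
  cat(sprintf("  bandwidth (%s 2-observer OPA range): %.*f\n",
              if (x$bandwidth_mode == "exact") "exact" else "sampled",
              digits, x$bandwidth))
  cat(sprintf("  plateau: k = %d at OPA %.*f (%s envelope, eps %g)\n",
              x$plateau_k, digits, x$plateau_value, x$plateau_on,
              x$plateau_eps))
  cat(sprintf("  OPA with all %d observers: %.*f\n",
              x$n_observers, digits, x$opa_all))
  invisible(x)
}

#' Exhaustive OPA envelopes by subset enumeration
#'
#' Pointwise minimum, maximum and mean OPA over *all* N! observer
#' orderings at each k = 2..N. Because the OPA of an ordering's length-k
#' prefix depends only on the prefix as a set, and every size-k subset is
#' the prefix of the same number of orderings, it suffices to enumerate the
#' `choose(N, k)` subsets per k (501 subset evaluations in total for
#' N = 9, against 362,880 orderings).
#'
#' @param x a `categorical_ratings` matrix.
#' @param max_observers guard on N (subset counts grow as 2^N).
#' @return list of class `onest_envelope` with `k`, `min_curve`,
#'   `max_curve`, `mean_curve`.
#' @export
exhaustive_envelope <- function(x, max_observers = 12) {
  stopifnot(inherits(x, "categorical_ratings"))
  N <- ncol(x)
  if (N > max_observers)
    stop("N = ", N, " exceeds the exhaustive guard (", max_observers,
         "); use onest() sampling instead", call. = FALSE)
  codes <- code_matrix(x)
  mins <- maxs <- means <- numeric(N - 1)
  for (k in 2:N) {
    opas <- utils::combn(N, k, function(s) {
      sub <- codes[, s, drop = FALSE]
      mean(rowSums(sub == sub[, 1]) == k)
    })
    mins[k - 1] <- min(opas)
    maxs[k - 1] <- max(opas)
    means[k - 1] <- mean(opas)
  }
  nm <- paste0("k", 2:N)
  structure(list(k = 2:N,
                 min_curve = stats::setNames(mins, nm),
                 max_curve = stats::setNames(maxs, nm),
                 mean_curve = stats::setNames(means, nm)),
            class = "onest_envelope")
}

#' Per-category unanimous case counts
#'
#' For each category label, the number of cases on which every observer
#' assigned that label. The counts sum to the number of fully agreed
#' cases, i.e. `opa_all * n_cases`.
#'
#' @param x a `categorical_ratings` matrix.
#' @return list with `counts` (named integer vector over the label set)
#'   and `total`.
#' @export
category_consensus_counts <- function(x) {
  stopifnot(inherits(x, "categorical_ratings"))
  m <- unclass_ratings(x)
  unanimous <- rowSums(m == m[, 1]) == ncol(m)
  counts <- table(factor(m[unanimous, 1], levels = attr(x, "label_set")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts, total = sum(counts))
}
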