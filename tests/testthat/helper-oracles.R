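# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths (prefix scans, subset enumeration,
# ANOVA shortcuts) so they can serve as references.

# the standard 4-case x 3-observer toy: rows (A,A,A),(A,A,B),(B,B,B),(A,B,B)
toy_matrix <- function() {
  categorical_ratings(rbind(c("A", "A", "A"), c("A", "A", "B"),
                            c("B", "B", "B"), c("A", "B", "B")),
                      label_set = c("A", "B"))
}

# sample one element of x (safe for length-1 x, unlike sample(x, 1))
pick <- function(x) x[sample.int(length(x), 1)]

random_cat_matrix <- function(n_cases, n_obs, n_labels = 3) {
  labs <- LETTERS[seq_len(n_labels)]
  categorical_ratings(matrix(sample(labs, n_cases * n_obs, replace = TRUE),
                             nrow = n_cases),
                      label_set = labs)
}

# OPA by literal definition: count rows whose selected entries are one value
opa_brute <- function(cm, obs) {
  m <- matrix(as.vector(cm), nrow = nrow(cm))[, obs, drop = FALSE]
  mean(apply(m, 1, function(r) length(unique(r)) == 1))
}

# all permutations of 1..n, recursively (independent of the package's
# lexicographic generator)
perms_brute <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_brute(n - 1)) {
    for (pos in 0:(n - 1)) out[[length(out) + 1L]] <- append(p, n, after = pos)
  }
  out
}

# pointwise envelopes over ALL n! permutations, each curve by repeated
# full-definition OPA calls on prefixes
envelope_brute <- function(cm) {
  N <- ncol(cm)
  curves <- do.call(rbind, lapply(perms_brute(N), function(p) {
    vapply(2:N, function(k) opa_brute(cm, p[1:k]), 0)
  }))
  list(min = apply(curves, 2, min), max = apply(curves, 2, max),
       mean = colMeans(curves), curves = curves)
}

# ICC(2,1) from scratch: explicit sums of squares, no shared code
icc_brute <- function(x) {
  n <- nrow(x); k <- ncol(x); g <- mean(x)
  ssr <- sum((rowMeans(x) - g)^2) * k
  ssc <- sum((colMeans(x) - g)^2) * n
  sse <- 0
  for (i in 1:n) for (j in 1:k) {
    sse <- sse + (x[i, j] - rowMeans(x)[i] - colMeans(x)[j] + g)^2
  }
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# tie-corrected Kruskal-Wallis H by hand: midranks and the standard
# correction divisor
kw_brute <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)  # midranks
  sizes <- vapply(groups, length, 1L)
  grp <- rep(seq_along(groups), sizes)
  rs <- tapply(r, grp, sum)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
  tie <- table(values)
  h / (1 - sum(tie^3 - tie) / (n^3 - n))
}
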