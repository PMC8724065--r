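test_that("OPA counts fully agreed cases", {
  m <- toy_matrix()
  expect_equal(compute_opa(m), 0.5)
  expect_equal(compute_opa(m, c(1, 2)), 0.75)
  expect_error(compute_opa(m, 1), "at least 2")
  expect_error(compute_opa(m, c(1, 4)), "out of range")
  expect_error(compute_opa(m, c(1, 1)), "duplicate")

  perfect <- categorical_ratings(matrix("A", 5, 4), label_set = c("A", "B"))
  expect_equal(compute_opa(perfect), 1)
  none <- categorical_ratings(rbind(c("A", "B"), c("B", "A")))
  expect_equal(compute_opa(none), 0)
})

test_that("OPA matches the brute-force all-equal-row count on random matrices", {
  set.seed(11)
  for (rep in 1:60) {
    cm <- random_cat_matrix(sample(1:12, 1), sample(2:5, 1), sample(2:4, 1))
    obs <- sample(seq_len(ncol(cm)), pick(2:ncol(cm)))
    expect_equal(compute_opa(cm, obs), opa_brute(cm, obs))
  }
})

test_that("an OPA curve is the OPA of growing prefixes and never increases", {
  m <- toy_matrix()
  expect_equal(unname(opac(m, 1:3)), c(0.75, 0.5))
  expect_error(opac(m, c(1, 2)), "permutation")
  expect_error(opac(m, c(1, 2, 2)), "permutation")
  set.seed(21)
  for (rep in 1:40) {
    cm <- random_cat_matrix(sample(3:10, 1), sample(3:6, 1))
    p <- sample(ncol(cm))
    cv <- opac(cm, p)
    expect_true(all(diff(cv) <= 1e-12))
    expect_equal(unname(cv[length(cv)]), compute_opa(cm))
    expect_equal(unname(cv),
                 vapply(2:ncol(cm), function(k) opa_brute(cm, p[1:k]), 0))
  }
})

test_that("permutation sampling is distinct, uniform-without-replacement and seeded", {
  expect_equal(count_permutations(9), 362880)
  expect_equal(count_permutations(1), 1)
  expect_equal(count_permutations(5), 120)

  p9 <- sample_permutations(9, 100, seed = 5)
  expect_equal(dim(p9), c(100, 9))
  keys <- apply(p9, 1, paste, collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
  expect_identical(p9, sample_permutations(9, 100, seed = 5))

  p3 <- sample_permutations(3, 10, seed = 1)
  expect_equal(nrow(p3), 6)  # all of 3!, capped
  expect_identical(p3, sample_permutations(3, 10, seed = 99))  # seed-free once exhaustive
  expect_true(all(apply(p3, 1, sort) == 1:3))
})

test_that("plateau detection uses the terminal-gap rule", {
  expect_equal(detect_plateau(c(1, 1, 1))$plateau_k, 2L)
  pl <- detect_plateau(c(0.9, 0.8, 0.7, 0.7, 0.7), eps = 0.02)
  expect_equal(pl$plateau_k, 4L)
  expect_equal(pl$plateau_value, 0.7)
  expect_equal(detect_plateau(c(0.9, 0.5, 0.1), eps = 1)$plateau_k, 2L)
})

test_that("onest summarizes curves, bandwidth, plateau and consensus", {
  m <- toy_matrix()
  res <- onest(m, n_perm = 10, seed = 2)
  expect_true(res$exhaustive)  # 10 >= 3!
  expect_equal(res$n_perm, 6)
  # pairwise OPAs: {1,2}=0.75, {1,3}=0.5, {2,3}=0.75
  expect_equal(unname(res$min_curve[1]), 0.5)
  expect_equal(unname(res$max_curve[1]), 0.75)
  expect_equal(res$opa_all, 0.5)
  expect_equal(res$bandwidth, 0.25)
  expect_equal(res$pair_opa_min, 0.5)
  expect_equal(res$consensus$counts, c(A = 1L, B = 1L))
  expect_equal(res$consensus$total, 2L)

  # smallest panel: two observers, a single-point curve
  two <- categorical_ratings(rbind(c("A", "A"), c("A", "B"), c("B", "B")))
  r2 <- onest(two, n_perm = 5, seed = 1)
  expect_equal(dim(r2$curves), c(2, 1))
  expect_equal(r2$opa_all, 2 / 3)
  expect_equal(r2$bandwidth, 0)

  perfect <- categorical_ratings(matrix("A", 5, 4), label_set = c("A", "B"))
  pres <- onest(perfect, n_perm = 30, seed = 1)
  expect_true(all(pres$min_curve == 1) && all(pres$max_curve == 1))
  expect_equal(pres$bandwidth, 0)
  expect_equal(pres$plateau_k, 2L)
  expect_equal(pres$opa_all, 1)
})

test_that("bandwidth arithmetic is max minus min two-observer OPA", {
  # max pairwise OPA 0.94 and min 0.76 give bandwidth 0.18
  set.seed(3)
  base <- matrix(sample(c("x", "y"), 100 * 3, TRUE), 100, 3)
  base[, 2] <- base[, 1]; base[, 3] <- base[, 1]
  base[1:6, 2] <- ifelse(base[1:6, 1] == "x", "y", "x")     # pair (1,2): 0.94
  base[1:24, 3] <- ifelse(base[1:24, 1] == "x", "y", "x")   # pair (1,3): 0.76
  res <- onest(categorical_ratings(base, label_set = c("x", "y")),
               n_perm = 6, seed = 1)
  expect_equal(res$pair_opa_max, 0.94)
  expect_equal(res$pair_opa_min, 0.76)
  expect_equal(res$bandwidth, 0.18)
})

test_that("exhaustive subset-enumeration envelopes equal all-permutation brute force", {
  set.seed(31)
  for (rep in 1:15) {
    cm <- random_cat_matrix(sample(3:8, 1), sample(3:5, 1))
    env <- exhaustive_envelope(cm)
    ref <- envelope_brute(cm)
    expect_equal(unname(env$min_curve), ref$min)
    expect_equal(unname(env$max_curve), ref$max)
    expect_equal(unname(env$mean_curve), ref$mean)
  }
  big <- random_cat_matrix(5, 13)
  expect_error(exhaustive_envelope(big), "guard")
})

test_that("sampled envelopes lie inside the exhaustive ones and converge at N", {
  set.seed(41)
  for (rep in 1:10) {
    cm <- random_cat_matrix(sample(5:12, 1), 5)
    res <- onest(cm, n_perm = 20, seed = rep)
    env <- exhaustive_envelope(cm)
    expect_true(all(res$min_curve >= env$min_curve - 1e-12))
    expect_true(all(res$max_curve <= env$max_curve + 1e-12))
    expect_true(all(res$min_curve <= res$mean_curve + 1e-12))
    expect_true(all(res$mean_curve <= res$max_curve + 1e-12))
    all_opa <- compute_opa(cm)
    expect_equal(unname(res$min_curve[4]), all_opa)
    expect_equal(unname(res$max_curve[4]), all_opa)
    expect_equal(unname(env$min_curve[4]), all_opa)
    expect_equal(res$consensus$total / res$n_cases, all_opa)
  }
})

test_that("min-envelope realizability is reported, not assumed", {
  set.seed(51)
  for (rep in 1:10) {
    cm <- random_cat_matrix(8, 5)
    res <- onest(cm, n_perm = 200, seed = rep)  # exhaustive: 120 perms
    realizes <- apply(res$curves, 1, function(cv) all(cv == res$min_curve))
    expect_equal(res$min_realized, any(realizes))
  }
  # a matrix whose pointwise minimum envelope is attained by no single
  # ordering: the worst pair at k = 2 cannot extend to the worst triple
  rows <- c("BCACB", "BACCC", "ABAAB", "ABBAB", "BABAA", "ACBBC",
            "ACBBB", "BBBAB", "AABAC", "CBBCA", "CAABC")
  cm <- categorical_ratings(do.call(rbind, strsplit(rows, "")),
                            label_set = c("A", "B", "C"))
  res <- onest(cm, n_perm = 1000, seed = 1)  # exhaustive: all 120 orderings
  expect_false(res$min_realized)
  ref <- envelope_brute(cm)
  expect_equal(unname(res$min_curve), ref$min)
  expect_false(any(apply(ref$curves, 1, function(cv) all(cv == ref$min))))
})

test_that("category consensus counts unanimous cases per label", {
  m <- toy_matrix()
  cc <- category_consensus_counts(m)
  expect_equal(cc$counts, c(A = 1L, B = 1L))
  expect_equal(cc$total, 2L)
  none <- categorical_ratings(rbind(c("A", "B"), c("B", "A")))
  expect_equal(category_consensus_counts(none)$total, 0L)
})
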