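test_that("marker profiles validate and the built-in set loads", {
  expect_error(marker_profile("bad", weight = c(0.5, 0.4), location = c(10, 90),
                              spread = c(1, 1), negative_mass = 0.2),
               "sum to 1")
  profs <- marker_profiles()
  expect_setequal(names(profs),
                  c("er_cnb", "er_exc", "pr_cnb", "pr_exc",
                    "ki67_cnb", "ki67_exc"))
  for (p in profs) {
    expect_s3_class(p, "marker_profile")
    expect_equal(sum(p$weight) + p$negative_mass, 1, tolerance = 1e-8)
  }
})

test_that("latent draws are seeded, bounded and respect the negative atom", {
  prof <- marker_profiles()$er_cnb
  x <- sample_latent(prof, 500, seed = 4)
  expect_identical(x, sample_latent(prof, 500, seed = 4))
  expect_true(all(x >= 0 & x <= 100))

  all_neg <- marker_profile("neg", weight = numeric(0), location = numeric(0),
                            spread = numeric(0), negative_mass = 1)
  expect_true(all(sample_latent(all_neg, 100, seed = 1) == 0))
})

test_that("ER-like latent medians sit near the positive extreme", {
  x <- sample_latent(marker_profiles()$er_cnb, 1000, seed = 9)
  expect_gte(stats::median(x), 85)
  expect_lte(stats::median(x), 100)
  # ER mass is far more concentrated near 100 than Ki67's mid-range mass
  ki <- sample_latent(marker_profiles()$ki67_cnb, 1000, seed = 9)
  expect_gt(stats::median(x), stats::median(ki) + 30)
})

test_that("zero noise and zero bias reproduce the rounded latent vector", {
  latent <- c(0, 3, 17, 48, 96, 100)
  m <- simulate_ratings(latent, observer_model(4, noise_scale = 0, bias_sd = 0,
                                               rounding_grid = 5), seed = 1)
  expected <- round(latent / 5) * 5
  for (j in 1:4) expect_equal(unname(unclass(m)[, j]), expected)
  cm <- categorize(m, scheme("stgallen2013"))
  expect_equal(compute_opa(cm), 1)
})

test_that("exact 0% cases are fixed points unless leak is enabled", {
  latent <- rep(0, 50)
  m <- simulate_ratings(latent, observer_model(5, noise_scale = 1), seed = 2)
  expect_true(all(unclass(m) == 0))
  leaky <- simulate_ratings(latent,
                            observer_model(5, noise_scale = 1,
                                           extreme_leak = 0.5), seed = 2)
  expect_gt(sum(unclass(leaky) > 0), 0)
})

test_that("panel agreement falls as observer noise rises", {
  s <- scheme("ki67_3cat")
  mean_opa <- function(noise) {
    mean(vapply(1:12, function(i) {
      latent <- sample_latent(marker_profiles()$ki67_cnb, 40, seed = 1000 + i)
      m <- simulate_ratings(latent,
                            observer_model(6, noise_scale = noise),
                            seed = 2000 + i)
      compute_opa(categorize(m, s))
    }, 0))
  }
  opas <- vapply(c(0.1, 0.5, 1.2), mean_opa, 0)
  expect_true(all(diff(opas) < 0))
})

test_that("case mix near the extremes yields higher agreement than mid-range mix", {
  s <- scheme("ki67_3cat")
  opa_for <- function(key, i) {
    latent <- sample_latent(marker_profiles()[[key]], 40, seed = 300 + i)
    m <- simulate_ratings(latent, observer_model(6, noise_scale = 0.5,
                                                 rounding_grid = 5),
                          seed = 400 + i)
    compute_opa(categorize(m, s))
  }
  er <- mean(vapply(1:12, function(i) opa_for("er_cnb", i), 0))
  ki <- mean(vapply(1:12, function(i) opa_for("ki67_cnb", i), 0))
  expect_gt(er, ki)
})

test_that("marker_panel composes the pieces reproducibly", {
  p <- marker_panel("Ki67", "CNB", n_cases = 30, n_observers = 5, seed = 6)
  expect_s3_class(p, "percent_ratings")
  expect_equal(dim(p), c(30, 5))
  expect_true(all(unclass(p) %% 5 == 0))  # Ki67 default 5% grid
  expect_identical(unclass(marker_panel("Ki67", "CNB", n_cases = 30,
                                        n_observers = 5, seed = 6)),
                   unclass(p))
  er <- marker_panel("ER", "EXC", n_cases = 30, n_observers = 5, seed = 6)
  expect_true(all(unclass(er) %% 1 == 0))  # 1% grid

  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ratings(p, f1)
  write_ratings(marker_panel("Ki67", "CNB", n_cases = 30, n_observers = 5,
                             seed = 6), f2)
  expect_identical(readLines(f1), readLines(f2))
})
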