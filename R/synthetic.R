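#' Marker profiles: latent staining-percentage distributions
#'
#' A marker profile describes the distribution of the *true* percentage of
#' stained tumour-cell nuclei across cases, as a mixture of logit-normal
#' components on the bounded 0-100 scale plus an atom of truly negative
#' (0%) cases. A component with `spread = 0` is a point mass, which is how
#' the easy-to-read 100% extreme is represented. Weights and
#' `negative_mass` must sum to 1.
#'
#' Built-in profiles (see [marker_profiles()]) emulate the case mix of
#' multi-rater breast-marker studies: ER concentrated near 100% with a
#' small negative fraction, PR widely dispersed, Ki67 in the low-to-mid
#' range — the feature that drives how reproducible each marker's
#' categorization is, since values near 0% and 100% are the easiest to
#' score consistently.
#'
#' @param name profile identifier.
#' @param weight,location,spread equal-length numeric vectors: mixture
#'   weight, component location (%, in \[0, 100\]) and spread on the logit
#'   scale (0 = point mass) for each component.
#' @param negative_mass probability of a truly 0% case.
#' @return object of class `marker_profile`.
#' @export
marker_profile <- function(name, weight, location, spread, negative_mass = 0) {
  stopifnot(length(weight) == length(location),
            length(weight) == length(spread),
            all(weight >= 0), all(spread >= 0),
            all(location >= 0 & location <= 100),
            negative_mass >= 0, negative_mass <= 1)
  if (abs(sum(weight) + negative_mass - 1) > 1e-8)
    stop("component weights plus negative_mass must sum to 1", call. = FALSE)
  structure(list(name = name, weight = weight, location = location,
                 spread = spread, negative_mass = negative_mass),
            class = "marker_profile")
}

#' @rdname marker_profile
#' @details `marker_profiles()` loads the versioned built-in profile set
#'   from the package's `marker_profiles.yaml`; profiles are keyed
#'   `<marker>_<specimen>`, e.g. `ki67_cnb`.
#' @export
marker_profiles <- function() {
  path <- system.file("extdata", "marker_profiles.yaml", package = "onest",
                      mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  lapply(raw$profiles, function(p) {
    comp <- do.call(rbind, lapply(p$components, as.data.frame))
    marker_profile(p$name, comp$weight, comp$location, comp$spread,
                   negative_mass = if (is.null(p$negative_mass)) 0 else p$negative_mass)
  })
}

#' Sample latent true percentages from a marker profile
#'
#' @param profile a `marker_profile`.
#' @param n_cases number of cases to draw.
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @return numeric vector of true percentages in \[0, 100\].
#' @export
sample_latent <- function(profile, n_cases, seed = NULL) {
  stopifnot(inherits(profile, "marker_profile"), n_cases >= 1)
  draw <- function() {
    probs <- c(profile$negative_mass, profile$weight)
    comp <- sample.int(length(probs), n_cases, replace = TRUE, prob = probs)
    out <- numeric(n_cases)
    for (i in seq_along(profile$weight)) {
      sel <- comp == i + 1L
      if (!any(sel)) next
      loc <- profile$location[i]; sp <- profile$spread[i]
      if (sp == 0 || loc == 0 || loc == 100) {
        out[sel] <- loc
      } else {
        out[sel] <- 100 * stats::plogis(stats::rnorm(sum(sel),
                                                     stats::qlogis(loc / 100),
                                                     sp))
      }
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Observer model: how a panel reads a latent percentage
#'
#' Each observer's reading of a case with true percentage p is
#' `inverse_logit(logit(p) + bias + noise)` on the 0-100 scale, rounded to
#' the reporting grid and clamped to \[0, 100\]. Noise is Gaussian on the
#' logit scale with standard deviation `noise_scale`, so reading spread
#' naturally shrinks near the 0% and 100% extremes. Per-observer systematic
#' offsets (`biases`, logit scale) default to draws from
#' `N(0, bias_sd^2)`. Exact 0% and 100% cases are fixed points — a truly
#' negative case is read negative — unless `extreme_leak > 0` gives each
#' observer-case read that probability of being re-scored as an ordinary
#' near-extreme value.
#'
#' @param n_observers panel size.
#' @param noise_scale SD of per-read estimation error on the logit scale.
#' @param bias_sd SD of per-observer systematic offsets (logit scale);
#'   ignored when `biases` is given.
#' @param biases optional numeric vector of per-observer offsets.
#' @param rounding_grid reporting grid in percent; must divide 100 (5 for
#'   Ki67-style eyeballing, 1 for ER/PR-style reporting).
#' @param extreme_leak probability that an exact 0/100 case is misread.
#' @return object of class `observer_model`.
#' @export
observer_model <- function(n_observers = 9, noise_scale = 0.5, bias_sd = 0.15,
                           biases = NULL, rounding_grid = 5,
                           extreme_leak = 0) {
  stopifnot(n_observers >= 2, noise_scale >= 0, bias_sd >= 0,
            extreme_leak >= 0, extreme_leak <= 1)
  if (100 %% rounding_grid != 0)
    stop("rounding_grid must divide 100", call. = FALSE)
  if (!is.null(biases) && length(biases) != n_observers)
    stop("need one bias per observer", call. = FALSE)
  structure(list(n_observers = n_observers, noise_scale = noise_scale,
                 bias_sd = bias_sd, biases = biases,
                 rounding_grid = rounding_grid, extreme_leak = extreme_leak),
            class = "observer_model")
}

#' Simulate a panel's percentage ratings of latent cases
#'
#' @param latent numeric vector of true percentages (from
#'   [sample_latent()]).
#' @param model an `observer_model`.
#' @param seed integer seed.
#' @return a `percent_ratings` matrix, cases x observers, on the model's
#'   rounding grid.
#' @export
simulate_ratings <- function(latent, model, seed = NULL) {
  stopifnot(inherits(model, "observer_model"),
            all(latent >= 0 & latent <= 100))
  draw <- function() {
    n <- length(latent)
    N <- model$n_observers
    biases <- model$biases
    if (is.null(biases)) biases <- stats::rnorm(N, 0, model$bias_sd)
    out <- matrix(0, nrow = n, ncol = N)
    extreme <- latent == 0 | latent == 100
    # interior values get shifted/jittered on the logit scale; a misread
    # extreme (leak) is re-scored as a borderline 1% / 99% case plus noise
    lg <- stats::qlogis(pmin(pmax(latent, 1e-6), 100 - 1e-6) / 100)
    lg[latent == 0] <- stats::qlogis(0.01)
    lg[latent == 100] <- stats::qlogis(0.99)
    for (j in seq_len(N)) {
      read <- 100 * stats::plogis(lg + biases[j] +
                                    stats::rnorm(n, 0, model$noise_scale))
      keep_extreme <- extreme &
        stats::runif(n) >= model$extreme_leak
      read[keep_extreme] <- latent[keep_extreme]
      out[, j] <- pmin(pmax(round(read / model$rounding_grid) *
                              model$rounding_grid, 0), 100)
    }
    out
  }
  vals <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  percent_ratings(vals)
}

#' Simulate a marker/specimen panel in one call
#'
#' Composes [sample_latent()] and [simulate_ratings()] with the built-in
#' profile for a marker and specimen type: `ER`, `PR` or `Ki67` scored on
#' core-needle biopsies (`CNB`) or excision specimens (`EXC`). Defaults —
#' 50 cases, 9 observers, 5% reporting grid for Ki67 and 1% otherwise —
#' match the design of typical multi-rater breast-marker panels.
#'
#' @param marker one of `"ER"`, `"PR"`, `"Ki67"`.
#' @param specimen one of `"CNB"`, `"EXC"`.
#' @param n_cases,n_observers panel dimensions.
#' @param seed integer seed (drives both the case draw and the panel
#'   reads).
#' @param noise_scale,bias_sd,extreme_leak observer-model parameters; see
#'   [observer_model()].
#' @param rounding_grid reporting grid; default 5 for Ki67, 1 otherwise.
#' @return a `percent_ratings` matrix.
#' @examples
#' p <- marker_panel("Ki67", "CNB", seed = 7)
#' onest(categorize(p, scheme("stgallen2013")), n_perm = 50, seed = 7)
#' @export
marker_panel <- function(marker = c("ER", "PR", "Ki67"),
                         specimen = c("CNB", "EXC"),
                         n_cases = 50, n_observers = 9, seed = NULL,
                         noise_scale = 0.5, bias_sd = 0.15,
                         extreme_leak = 0, rounding_grid = NULL) {
  marker <- match.arg(marker)
  specimen <- match.arg(specimen)
  key <- paste0(tolower(marker), "_", tolower(specimen))
  profile <- marker_profiles()[[key]]
  if (is.null(profile)) stop("no built-in profile '", key, "'", call. = FALSE)
  if (is.null(rounding_grid)) rounding_grid <- if (marker == "Ki67") 5 else 1
  model <- observer_model(n_observers = n_observers,
                          noise_scale = noise_scale, bias_sd = bias_sd,
                          rounding_grid = rounding_grid,
                          extreme_leak = extreme_leak)
  run <- function() {
    latent <- sample_latent(profile, n_cases)
    simulate_ratings(latent, model)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
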