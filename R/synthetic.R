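# Synthetic calibration data: densitometry-style time series of deposited
# species generated from known ground-truth parameters, used for
# parameter-recovery experiments and pipeline tests. The study design is
# eight time points over 0-3.5 h; on PC surfaces the observed deposited
# species are CRP, C4, C3 and C4BP, on GlcNAc surfaces MASP-2, C4, C3 and
# C4BP.

#' Noise model for synthetic observations
#'
#' Multiplicative log-normal noise (mean 1, coefficient of variation `cv`)
#' is the default, a plausible error structure for densitometric band
#' quantification; additive Gaussian noise is available as an alternative.
#'
#' @param kind `"multiplicative-lognormal"` or `"additive-gaussian"`.
#' @param cv coefficient of variation (multiplicative kind).
#' @param sd standard deviation in nM (additive kind).
#' @return a `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative-lognormal",
                                 "additive-gaussian"),
                        cv = 0.1, sd = 0) {
  kind <- match.arg(kind)
  stopifnot(cv >= 0, sd >= 0)
  structure(list(kind = kind, cv = cv, sd = sd), class = "noise_model")
}

apply_noise <- function(x, noise) {
  if (noise$kind == "multiplicative-lognormal") {
    if (noise$cv == 0) return(x)
    sdlog <- sqrt(log(1 + noise$cv^2))
    x * rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    x + rnorm(length(x), sd = noise$sd)
  }
}

#' Default sampling times of the study design
#'
#' Eight equally spaced time points over 0 to 3.5 h, in seconds, snapped to
#' the 100 s simulation grid.
#'
#' @return numeric vector of length 8.
#' @export
default_sample_times <- function() {
  round(seq(0, 12600, length.out = 8) / 100) * 100
}

#' Generate a synthetic calibration dataset
#'
#' Simulates each condition at the ground-truth parameter vector, samples
#' the observed species at the sampling times, applies the noise model, and
#' scale-normalises each series (dividing by the series mean, the same
#' normalisation the estimation objectives use) (the same normalisation the estimation
#' objectives use). The ground truth and seed are recorded, so the
#' generator closes the loop with [estimate_two_stage()] in recovery
#' experiments.
#'
#' @param network a `reaction_network`.
#' @param theta_true named vector of true values for the unknown
#'   parameters.
#' @param conditions named list of [condition()] objects or `NULL` entries.
#' @param observed named list (per condition label) of observed species;
#'   defaults to all network species for every condition.
#' @param sample_times observation times (must be reachable by simulation;
#'   default the study's 8 points over 0-3.5 h).
#' @param noise a [noise_model()].
#' @param seed RNG seed.
#' @param affinity_model optional, for conditions away from the reference.
#' @param normalise scale each series by its mean (the estimation
#'   objectives' arbitrary-units convention); with `FALSE` the values stay
#'   in nM and each series gets weight `1/max(series)^2`, the balanced
#'   absolute-scale convention used by the sensitivity analysis.
#' @return a [dataset()] with attributes `theta_true`, `seed`, `noise`.
#' @export
generate_dataset <- function(network, theta_true,
                             conditions = list(baseline = NULL),
                             observed = NULL,
                             sample_times = default_sample_times(),
                             noise = noise_model(), seed = 1,
                             affinity_model = NULL, normalise = TRUE) {
  set.seed(seed)
  rows <- NULL
  for (lab in names(conditions)) {
    net <- realize_condition(network, conditions[[lab]], affinity_model)
    times <- sort(unique(c(0, sample_times)))
    traj <- simulate(net, grid = times, params = theta_true,
                     check_conservation = FALSE)
    species <- observed[[lab]] %||% network$species$name
    for (s in species) {
      y <- series(traj, s, net)[match(sample_times, times)]
      y <- pmax(apply_noise(y, noise), 0)
      rows <- rbind(rows, data.frame(
        condition = lab, species = s, time_s = sample_times,
        value = if (normalise) normalise_series(y) else y,
        weight = if (normalise) 1 else 1 / max(y)^2))
    }
  }
  ds <- dataset(rows, conditions)
  attr(ds, "theta_true") <- theta_true
  attr(ds, "seed") <- seed
  attr(ds, "noise") <- noise
  ds
}

#' Small test-model library
#'
#' Closed-form-friendly reaction networks used throughout the test suite so
#' that DBN, inference and estimation tests never require the full
#' complement model:
#' * `"decay1"`: one species, first-order decay (`x(t) = x0 exp(-k t)`).
#' * `"chain2"`: A -> B mass action.
#' * `"cascade3"`: A -> B -> C linear cascade with losses; four unknown
#'   rate constants, all identifiable from the three species' time courses.
#' * `"mm2"`: Michaelis-Menten cleavage of S by a constant enzyme E.
#'
#' @param name model name.
#' @param x0 optional named initial-concentration overrides.
#' @return a `reaction_network`.
#' @export
toy_model <- function(name = c("decay1", "chain2", "cascade3", "mm2"),
                      x0 = NULL) {
  name <- match.arg(name)
  net <- switch(
    name,
    decay1 = build_network(
      species = data.frame(name = "A", role = "fluid-phase", init = 100),
      reactions = list(
        reaction("r1", "A", character(), rate_law("mass_action", k = "k1"))),
      params = data.frame(name = "k1", value = 0.01, lo = 0.001, hi = 0.05,
                          known = FALSE),
      meta = list(name = "decay1")),
    chain2 = build_network(
      species = data.frame(name = c("A", "B"), role = "fluid-phase",
                           init = c(100, 0)),
      reactions = list(
        reaction("r1", "A", "B", rate_law("mass_action", k = "k1"))),
      params = data.frame(name = "k1", value = 0.01, lo = 0.001, hi = 0.05,
                          known = FALSE),
      conservation = list(total = c("A", "B")),
      meta = list(name = "chain2")),
    cascade3 = build_network(
      species = data.frame(name = c("A", "B", "C"), role = "fluid-phase",
                           init = c(100, 0, 0)),
      reactions = list(
        reaction("r1", "A", "B", rate_law("mass_action", k = "k1")),
        reaction("r2", "B", "C", rate_law("mass_action", k = "k2")),
        reaction("r3", "B", "A", rate_law("mass_action", k = "k3")),
        reaction("r4", "C", character(), rate_law("mass_action", k = "k4"))),
      params = data.frame(name = c("k1", "k2", "k3", "k4"),
                          value = c(2.6e-3, 1.6e-3, 1.6e-3, 2.6e-3),
                          lo = 1e-4, hi = 5.1e-3, known = FALSE),
      meta = list(name = "cascade3")),
    mm2 = build_network(
      species = data.frame(name = c("E", "S", "P"), role = "fluid-phase",
                           init = c(2, 100, 0)),
      reactions = list(
        reaction("r1", "S", "P", rate_law("michaelis_menten", c = "kc",
                                          c_half = "km"),
                 modifiers = "E")),
      params = data.frame(name = c("kc", "km"), value = c(0.5, 20),
                          lo = c(0.05, 2), hi = c(2, 100), known = FALSE),
      conservation = list(total_S = c("S", "P")),
      meta = list(name = "mm2")))
  if (!is.null(x0)) net$species$init[match(names(x0), net$species$name)] <- x0
  net
}
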