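# Seeded generator of grazing-experiment count data. The generative model
# is the one the Heinbokel estimator assumes: exogenous exponential
# predator dynamics and prey removal proportional to clearance x predator
# concentration, with an exact closed-form trajectory.

#' Simulator parameters
#'
#' Parameters of the batch predator-prey model
#' `dB/dt = (k - F_true * C(t)) * B`, `C(t) = C0 * exp(mu_c * t)`:
#' prey grows at intrinsic rate `k` and is cleared at rate `F_true`
#' (mL predator^-1 day^-1) by a predator population growing exponentially at
#' `mu_c` (independently of prey: freshwater ciliates regrow on bacteria or
#' by cannibalism after prey depletion, so predator yield is not modelled).
#' Observation noise emulates counting error: `"lognormal"` multiplies each
#' count by `exp(N(0, sigma^2))`; `"poisson"` draws the number of cells seen
#' in a counted aliquot of `count_volume` mL.
#'
#' @param k Prey intrinsic growth rate (day^-1). Default 0.074, a typical
#'   slow raphidophyte monoculture rate.
#' @param F_true Clearance rate (mL predator^-1 day^-1), >= 0.
#' @param C0 Initial predator concentration (cells mL^-1), >= 0; 0 gives a
#'   monoculture. Default 200.
#' @param mu_c Predator growth rate (day^-1); 0 = constant predator.
#' @param B0 Initial prey concentration (cells mL^-1), > 0. Default 1000.
#' @param noise `"none"`, `"lognormal"` or `"poisson"`.
#' @param sigma Lognormal noise SD on the log scale (default 0.1, a
#'   plausible settling-chamber counting error).
#' @param count_volume Counted aliquot volume in mL for Poisson noise
#'   (default 1).
#' @param seed Integer seed for the noise draws; `NULL` uses the current
#'   RNG stream.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(k = 0.074, F_true = 0, C0 = 200, mu_c = 0, B0 = 1000,
                       noise = c("none", "lognormal", "poisson"),
                       sigma = 0.1, count_volume = 1, seed = NULL) {
  noise <- match.arg(noise)
  for (nm in c("k", "F_true", "C0", "mu_c", "B0")) {
    if (!is_scalar_number(get(nm)))
      gk_domain_error(sprintf("%s must be a finite numeric scalar", nm))
  }
  if (B0 <= 0) gk_domain_error("B0 must be > 0")
  if (C0 < 0) gk_domain_error("C0 must be >= 0")
  if (F_true < 0) gk_domain_error("F_true must be >= 0")
  if (noise == "lognormal" && (!is_scalar_number(sigma) || sigma <= 0))
    gk_domain_error("sigma must be > 0 for lognormal noise")
  if (noise == "poisson" && (!is_scalar_number(count_volume) || count_volume <= 0))
    gk_domain_error("count_volume must be > 0 for poisson noise")
  structure(list(k = k, F_true = F_true, C0 = C0, mu_c = mu_c, B0 = B0,
                 noise = noise, sigma = sigma, count_volume = count_volume,
                 seed = seed),
            class = "sim_params")
}

# ln B(t) under the closed-form solution; the mu_c -> 0 limit is F*C0*t.
prey_log_trajectory <- function(t, params) {
  with(params, {
    graze <- if (mu_c == 0) F_true * C0 * t
    else F_true * C0 * (exp(mu_c * t) - 1) / mu_c
    log(B0) + k * t - graze
  })
}

apply_noise <- function(conc, params) {
  switch(params$noise,
    none = conc,
    lognormal = conc * exp(stats::rnorm(length(conc), 0, params$sigma)),
    poisson = stats::rpois(length(conc), conc * params$count_volume) / params$count_volume)
}

#' Simulate one grazed (or monoculture) flask
#'
#' Evaluates the closed-form trajectory of the [sim_params()] model at the
#' sampling days and applies the observation-noise model, seeded. Noise is
#' drawn per sampling time for prey and predator counts alike.
#'
#' @param params A [sim_params()] object.
#' @param days Sampling days, strictly increasing, starting at 0.
#' @param flask_id,prey_strain,predator_strain Labels for the returned
#'   series (`predator_strain` ignored for monocultures).
#' @return A [count_series()]; `treatment` is `"grazed"` when `C0 > 0`.
#' @examples
#' simulate_grazing(sim_params(k = 0.074, F_true = 1e-4, mu_c = 0.23))
#' @export
simulate_grazing <- function(params, days = seq(0, 20, by = 2),
                             flask_id = "sim1", prey_strain = "sim_prey",
                             predator_strain = "sim_predator") {
  stopifnot(inherits(params, "sim_params"))
  days <- as.numeric(days)
  if (length(days) < 2 || any(diff(days) <= 0) || days[1] != 0)
    gk_domain_error("days must be strictly increasing and start at 0")
  prey <- exp(prey_log_trajectory(days, params))
  pred <- params$C0 * exp(params$mu_c * days)
  obs <- with_seed(params$seed, {
    p1 <- apply_noise(prey, params)
    p2 <- if (params$C0 > 0) apply_noise(pred, params) else pred
    list(prey = p1, pred = p2)
  })
  count_series(flask_id = flask_id, prey_strain = prey_strain,
               treatment = if (params$C0 > 0) "grazed" else "control",
               days = days, prey_conc = pmax(obs$prey, 0),
               predator_conc = pmax(obs$pred, 0),
               predator_strain = if (params$C0 > 0) predator_strain else NULL)
}

#' Simulate a prey monoculture flask
#'
#' [simulate_grazing()] with `C0 = 0`: pure exponential prey growth plus
#' observation noise.
#'
#' @inheritParams sim_params
#' @inheritParams simulate_grazing
#' @return A control [count_series()].
#' @export
simulate_monoculture <- function(k = 0.074, B0 = 1000, days = seq(0, 20, by = 2),
                                 noise = "none", sigma = 0.1, count_volume = 1,
                                 seed = NULL, flask_id = "mono1",
                                 prey_strain = "sim_prey") {
  simulate_grazing(
    sim_params(k = k, F_true = 0, C0 = 0, mu_c = 0, B0 = B0, noise = noise,
               sigma = sigma, count_volume = count_volume, seed = seed),
    days = days, flask_id = flask_id, prey_strain = prey_strain)
}

# Scenario parameter sets. These are fixed study conditions, not tuning
# knobs: 1000 prey and 200 predators per mL at day 0, sampling every 2 days
# for 20 days, prey intrinsic growth 0.074 d^-1, lognormal counting noise
# sigma = 0.1. The strong grazer depletes prey to a few percent of start
# while its population rises ~100-fold; the weak grazer leaves prey within
# 50-100% of the control; the null grazer does not feed on the prey at all
# (its population still grows, as if on an alternative food source).
scenario_params <- function(scenario) {
  switch(scenario,
    strong_grazer = list(F_true = 5e-5, mu_c = log(100) / 20),
    weak_grazer = list(F_true = 2e-5, mu_c = log(1.14)),
    null = list(F_true = 0, mu_c = log(1.14)))
}

#' Generate a full fixture grazing experiment
#'
#' Emits the complete experimental design — 3 prey strains, each with an
#' ungrazed control and one grazed flask per each of 2 predator strains
#' (9 flasks), sampled on days 0, 2, ..., 20 from 1000 prey mL^-1 and
#' 200 predators mL^-1 — under one of three scenarios:
#' \describe{
#'   \item{`strong_grazer`}{clearance 5e-5 mL pred^-1 d^-1, predator rising
#'     100-fold over 20 days; prey is driven below 10% of its start.}
#'   \item{`weak_grazer`}{clearance 2e-5, modest predator growth; grazed
#'     prey ends within 50-100% of the control.}
#'   \item{`null`}{clearance 0: grazed flasks are distributed exactly like
#'     controls (the predator grows but does not touch the prey).}
#' }
#'
#' @param scenario `"strong_grazer"`, `"weak_grazer"` or `"null"`.
#' @param seed Integer seed; the whole design is generated from one seeded
#'   stream, so equal seeds give bit-identical experiments.
#' @param noise,sigma Observation-noise model (defaults lognormal, 0.1).
#' @param days Sampling days.
#' @return A list of class `grazing_fixture`: `experiment` (an
#'   [experiment()]) and `truth` (the generating parameters).
#' @examples
#' fx <- make_fixture_experiment("strong_grazer", seed = 1)
#' fx$truth$F_true
#' @export
make_fixture_experiment <- function(scenario = c("strong_grazer", "weak_grazer", "null"),
                                    seed = 1L, noise = "lognormal", sigma = 0.1,
                                    days = seq(0, 20, by = 2)) {
  scenario <- match.arg(scenario)
  sp <- scenario_params(scenario)
  k <- 0.074; B0 <- 1000; C0 <- 200
  preys <- c("preyA", "preyB", "preyC")
  grazers <- c("grazerA", "grazerB")
  series <- with_seed(seed, {
    out <- list()
    for (p in preys) {
      out[[length(out) + 1L]] <- simulate_monoculture(
        k = k, B0 = B0, days = days, noise = noise, sigma = sigma,
        seed = NULL, flask_id = paste0(p, "_ctrl"), prey_strain = p)
      for (g in grazers) {
        out[[length(out) + 1L]] <- simulate_grazing(
          sim_params(k = k, F_true = sp$F_true, C0 = C0, mu_c = sp$mu_c,
                     B0 = B0, noise = noise, sigma = sigma, seed = NULL),
          days = days, flask_id = paste0(p, "_", g), prey_strain = p,
          predator_strain = g)
      }
    }
    out
  })
  structure(list(
    experiment = experiment(series),
    truth = list(scenario = scenario, k = k, F_true = sp$F_true, C0 = C0,
                 mu_c = sp$mu_c, B0 = B0, noise = noise, sigma = sigma,
                 days = days, seed = seed)),
    class = "grazing_fixture")
}

#' @export
print.grazing_fixture <- function(x, ...) {
  cat(sprintf("<grazing_fixture> scenario '%s' (seed %s)\n",
              x$truth$scenario, format(x$truth$seed)))
  cat(sprintf("  truth: k = %g, F_true = %g, C0 = %g, mu_c = %.4g, B0 = %g, noise = %s\n",
              x$truth$k, x$truth$F_true, x$truth$C0, x$truth$mu_c,
              x$truth$B0, x$truth$noise))
  print(x$experiment)
  invisible(x)
}
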