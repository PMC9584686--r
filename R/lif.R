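# Leaky integrate-and-fire neuron: membrane dynamics
#     tau_m dV/dt = -V(t) + R_m I(t),   tau_m = R_m C_m
# Under constant supra-threshold drive the membrane, interspike interval and
# firing rate have closed forms; an error-driven rule evolves tau_m during
# training so that neurons at different network positions diversify.

#' Membrane constants of a leaky integrate-and-fire neuron
#'
#' Any two of `resistance`, `capacitance` and `tau_m` determine the third via
#' `tau_m = resistance * capacitance`.
#'
#' @param resistance Membrane resistance `R_m` (arbitrary units, > 0).
#' @param capacitance Membrane capacitance `C_m` (> 0), optional if `tau_m`
#'   is given.
#' @param tau_m Membrane time constant (> 0), optional if `capacitance` is
#'   given.
#' @param threshold Firing threshold `V_th` (> reset_potential).
#' @param reset_potential Post-spike membrane value (default 0, the resting
#'   potential).
#' @param dt Integration time step; defaults to `tau_m / 100`. A warning is
#'   issued when `dt > tau_m / 10`, where explicit Euler becomes coarse.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(resistance = 1, capacitance = NULL, tau_m = NULL,
                       threshold = 1, reset_potential = 0, dt = NULL) {
  if (resistance <= 0) stop("`resistance` must be > 0", call. = FALSE)
  if (is.null(tau_m) && is.null(capacitance))
    stop("give `tau_m` or `capacitance`", call. = FALSE)
  if (is.null(tau_m)) tau_m <- resistance * capacitance
  if (is.null(capacitance)) capacitance <- tau_m / resistance
  if (abs(tau_m - resistance * capacitance) > 1e-8 * tau_m)
    stop("`tau_m` must equal `resistance * capacitance`", call. = FALSE)
  if (tau_m <= 0) stop("`tau_m` must be > 0", call. = FALSE)
  if (threshold <= reset_potential)
    stop("`threshold` must exceed `reset_potential`", call. = FALSE)
  dt <- dt %||% (tau_m / 100)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (dt > tau_m / 10)
    warning("`dt` exceeds tau_m/10; integration will be coarse", call. = FALSE)
  structure(list(resistance = resistance, capacitance = capacitance,
                 tau_m = tau_m, threshold = threshold,
                 reset_potential = reset_potential, dt = dt),
            class = "lif_params")
}

#' Closed-form sub-threshold membrane potential
#'
#' Under constant current `I0` from the reset potential 0, the membrane
#' follows `V(t) = R * I0 * (1 - exp(-t / tau_m))`.
#'
#' @param params A [lif_params()].
#' @param current Constant input current `I0`.
#' @param elapsed Time since the last reset (vectorised, >= 0).
#' @return Membrane potential(s).
#' @export
membrane_closed_form <- function(params, current, elapsed) {
  if (any(elapsed < 0)) stop("`elapsed` must be >= 0", call. = FALSE)
  params$resistance * current * (1 - exp(-elapsed / params$tau_m))
}

#' Closed-form interspike interval under constant drive
#'
#' `T = tau_m * ln(R*I0 / (R*I0 - V_th))`, defined only for supra-threshold
#' drive `R*I0 > V_th`.
#'
#' @inheritParams membrane_closed_form
#' @return The interspike interval (positive scalar).
#' @export
interspike_interval <- function(params, current) {
  drive <- params$resistance * current
  if (drive <= params$threshold)
    stop("sub-threshold drive: R*I0 <= threshold, the neuron never fires",
         call. = FALSE)
  params$tau_m * log(drive / (drive - params$threshold))
}

#' Closed-form firing rate under constant drive
#'
#' The reciprocal interspike interval for supra-threshold drive, 0
#' otherwise. At fixed drive the rate decreases strictly with `tau_m`, which
#' is what makes the time constant an effective per-neuron rate control.
#'
#' @inheritParams membrane_closed_form
#' @return Spikes per time unit (non-negative scalar).
#' @export
firing_rate <- function(params, current) {
  drive <- params$resistance * current
  if (drive <= params$threshold) return(0)
  1 / (params$tau_m * log(drive / (drive - params$threshold)))
}

#' Simulate a leaky integrate-and-fire neuron
#'
#' Explicit-Euler integration of the membrane equation,
#' `V <- V + (dt/tau_m) * (-V + R * I(t))`, starting at the reset potential.
#' When `V` reaches the threshold a spike time is recorded, the membrane is
#' reset and integration is suppressed for `refractory` time units.
#'
#' @param params A [lif_params()].
#' @param current Numeric vector: the input current at each time step.
#' @param refractory Absolute refractory period (time units, default 0).
#' @return An object of class `lif_trace`: a list with `trace` (a tibble
#'   with columns `time` and `membrane`, recorded after each update) and
#'   `spikes` (numeric spike times).
#' @export
lif_simulate <- function(params, current, refractory = 0) {
  if (length(current) == 0) stop("`current` must be non-empty", call. = FALSE)
  if (refractory < 0) stop("`refractory` must be >= 0", call. = FALSE)
  dt <- params$dt; tau <- params$tau_m
  n <- length(current)
  v <- numeric(n)
  spikes <- numeric(0)
  vm <- params$reset_potential
  blocked_until <- -Inf
  for (i in seq_len(n)) {
    t <- i * dt
    if (t >= blocked_until) {
      vm <- vm + (dt / tau) * (-vm + params$resistance * current[i])
      if (vm >= params$threshold) {
        spikes <- c(spikes, t)
        vm <- params$reset_potential
        blocked_until <- t + refractory
      }
    }
    v[i] <- vm
  }
  structure(list(trace = tibble::tibble(time = dt * seq_len(n), membrane = v),
                 spikes = spikes, params = params),
            class = "lif_trace")
}

#' @export
print.lif_trace <- function(x, ...) {
  cat(sprintf("<lif_trace> %d steps (dt = %g), %d spikes\n",
              nrow(x$trace), x$params$dt, length(x$spikes)))
  invisible(x)
}

#' Time-constant evolution rule
#'
#' After each training epoch every neuron's `tau_m` is rescaled by
#' `exp(rate * E)` where `E` is the epoch's output error, then clipped to
#' `tau_bounds`. Two semantics are provided: `"anchored"` rescales the
#' neuron's initial value (so `E -> 0` returns `tau_m` to `tau_init`, and
#' with `rate < 0` the time constant shrinks while the error is large, then
#' relaxes back, damping late-training rate oscillation) and `"recurrent"`
#' compounds the factor onto the previous epoch's value. Anchored is the
#' default; see the package vignette for the rationale.
#'
#' @param rate Evolution gain `a` (negative values shrink `tau_m` under
#'   error).
#' @param tau_init Initial time constant (> 0).
#' @param tau_bounds Length-2 positive bounds within which `tau_m` is kept.
#' @param mode `"anchored"` or `"recurrent"`.
#' @return An object of class `tau_rule`.
#' @export
tau_rule <- function(rate = -0.1, tau_init = 10, tau_bounds = c(1, 100),
                     mode = c("anchored", "recurrent")) {
  mode <- match.arg(mode)
  if (tau_init <= 0) stop("`tau_init` must be > 0", call. = FALSE)
  if (length(tau_bounds) != 2 || any(tau_bounds <= 0) ||
      tau_bounds[1] > tau_bounds[2])
    stop("`tau_bounds` must be two increasing positive numbers", call. = FALSE)
  structure(list(rate = rate, tau_init = tau_init, tau_bounds = tau_bounds,
                 mode = mode),
            class = "tau_rule")
}

#' Evolve a membrane time constant with the training error
#'
#' @param rule A [tau_rule()].
#' @param tau_prev Current time constant(s) (vectorised).
#' @param error Non-negative epoch error `E`.
#' @param tau_init Per-neuron initial values used in anchored mode; defaults
#'   to `rule$tau_init` (recycled).
#' @return Updated time constant(s), clipped to `rule$tau_bounds`.
#' @export
evolve_tau <- function(rule, tau_prev, error, tau_init = rule$tau_init) {
  if (!all(is.finite(error)) || any(error < 0))
    stop("`error` must be finite and >= 0", call. = FALSE)
  base <- if (rule$mode == "anchored") tau_init else tau_prev
  pmin(pmax(base * exp(rule$rate * error), rule$tau_bounds[1]),
       rule$tau_bounds[2])
}

# per-neuron initial time constants: tau_init times uniform jitter in
# [0.9, 1.1], the source of neuron diversity
jitter_tau <- function(tau_init, n, seed = NULL) {
  with_preserved_seed(seed, tau_init * stats::runif(n, 0.9, 1.1))
}
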