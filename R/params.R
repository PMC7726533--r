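#' Postsynaptic neuron parameters
#'
#' Membrane and synapse constants of the conductance-based leaky
#' integrate-and-fire (LIF) neuron.  Defaults are the standard parameter set
#' used throughout the package: a 30 ms membrane, excitatory/inhibitory
#' reversal potentials at 0/-80 mV, conductance decay constants of 5 ms (E)
#' and 10 ms (I), threshold -50 mV, reset and rest at -65 mV, a 5 ms
#' refractory period and a 0.1 ms integration step.
#'
#' Units: all times in ms, all voltages in mV.  Conductances are
#' dimensionless (in units of the leak conductance), so synaptic weights are
#' dimensionless conductance jumps.
#'
#' @param tau_m membrane time constant (ms)
#' @param u_rest resting potential (mV)
#' @param E_E excitatory reversal potential (mV)
#' @param E_I inhibitory reversal potential (mV)
#' @param tau_E excitatory conductance time constant (ms)
#' @param tau_I inhibitory conductance time constant (ms)
#' @param u_th spiking threshold (mV)
#' @param u_reset reset potential (mV)
#' @param tau_ref absolute refractory period (ms)
#' @param dt integration time step (ms); must not exceed
#'   `min(tau_E, tau_I)/10`
#' @return an object of class `neuron_params` (a validated named list)
#' @export
neuron_params <- function(tau_m = 30, u_rest = -65, E_E = 0, E_I = -80,
                          tau_E = 5, tau_I = 10, u_th = -50, u_reset = -65,
                          tau_ref = 5, dt = 0.1) {
  p <- list(tau_m = tau_m, u_rest = u_rest, E_E = E_E, E_I = E_I,
            tau_E = tau_E, tau_I = tau_I, u_th = u_th, u_reset = u_reset,
            tau_ref = tau_ref, dt = dt)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("neuron_params: '", nm, "' must be a finite scalar")
  }
  if (!(E_I < u_rest && u_rest <= u_reset && u_reset < u_th && u_th < E_E))
    stop("neuron_params: require E_I < u_rest <= u_reset < u_th < E_E")
  if (any(c(tau_m, tau_E, tau_I, tau_ref, dt) <= 0))
    stop("neuron_params: all time constants and dt must be > 0")
  if (dt > min(tau_E, tau_I) / 10)
    stop("neuron_params: dt must be <= min(tau_E, tau_I)/10 for a stable Euler step")
  structure(p, class = "neuron_params")
}

#' Firing-rate parameters for natural (OU-modulated) input
#'
#' Rates of the rectified Ornstein-Uhlenbeck modulation.  Each signal group
#' mu carries a latent variable `y` and afferents of population X fire as an
#' inhomogeneous Poisson process with rate
#' `nu_X0 * max(y, 0) + nu_Xbg` (Hz), suppressed during a per-afferent
#' refractory period.  Inhibitory populations additionally carry a gain
#' multiplier used for modulation experiments (gain 0 silences a
#' population; gain 1 is the control condition).
#'
#' @param nu_E0,nu_I0 modulation amplitude (Hz) for excitatory/inhibitory
#'   afferents
#' @param nu_Ebg,nu_Ibg background rate (Hz)
#' @param tau_Eref,tau_Iref presynaptic refractory period (ms)
#' @param tau_OU OU time constant (ms)
#' @param dT OU update step (ms); the rate is held constant between updates
#' @return an object of class `rate_params`
#' @export
rate_params <- function(nu_E0 = 5, nu_I0 = 10, nu_Ebg = 2, nu_Ibg = 4,
                        tau_Eref = 5, tau_Iref = 2.5, tau_OU = 50, dT = 1) {
  p <- list(nu_E0 = nu_E0, nu_I0 = nu_I0, nu_Ebg = nu_Ebg, nu_Ibg = nu_Ibg,
            tau_Eref = tau_Eref, tau_Iref = tau_Iref, tau_OU = tau_OU, dT = dT)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("rate_params: '", nm, "' must be a finite scalar")
  }
  if (any(c(nu_E0, nu_I0, nu_Ebg, nu_Ibg) < 0))
    stop("rate_params: rates must be >= 0")
  if (tau_OU <= 0 || dT <= 0 || tau_Eref < 0 || tau_Iref < 0)
    stop("rate_params: time constants must be positive")
  structure(p, class = "rate_params")
}

#' Pulse-input parameters
#'
#' A 100 ms step increase of the firing rate of a single signal group:
#' during the pulse the target group's rate is `alpha_X * k * nu_star +
#' nu_Xbg` (Hz) for population X, every other group (and the target group
#' outside the pulse window) stays at background.
#'
#' @param nu_star rate quantum (Hz); pulse amplitudes are integer multiples
#'   `k * nu_star`
#' @param k integer amplitude multiplier (>= 0)
#' @param alpha_E,alpha_I population-specific amplitude scalars
#' @param duration pulse duration (ms)
#' @param target_group index of the stimulated signal group
#' @return an object of class `pulse_params`
#' @export
pulse_params <- function(nu_star = 5, k = 0L, alpha_E = 1, alpha_I = 2,
                         duration = 100, target_group = 1L) {
  if (length(k) != 1L || k < 0 || k != round(k))
    stop("pulse_params: k must be a single integer >= 0")
  if (nu_star < 0 || duration <= 0)
    stop("pulse_params: nu_star >= 0 and duration > 0 required")
  structure(list(nu_star = nu_star, k = as.integer(round(k)),
                 alpha_E = alpha_E, alpha_I = alpha_I,
                 duration = duration, target_group = as.integer(target_group)),
            class = "pulse_params")
}

#' Excitatory tuning-profile parameters
#'
#' The bell-shaped weight profile over signal groups,
#' `r(mu) = 1/(1+r0) + (r0/(1+r0)) / (1 + b*(mu - mu0)^c)`,
#' maximal (value 1) at the preferred group `mu0`.  Group indices are
#' 1-based.
#'
#' @param r0 profile amplitude (>= 1)
#' @param b profile slope (0 < b <= 1)
#' @param c even positive integer power
#' @param mu0 preferred signal-group index
#' @return an object of class `tuning_params`
#' @export
tuning_params <- function(r0 = 4, b = 0.25, c = 2L, mu0 = 9L) {
  if (r0 < 1) stop("tuning_params: r0 must be >= 1")
  if (b <= 0 || b > 1) stop("tuning_params: b must satisfy 0 < b <= 1")
  if (c <= 0 || c != round(c) || (c %% 2) != 0)
    stop("tuning_params: c must be an even positive integer")
  if (mu0 < 1 || mu0 != round(mu0)) stop("tuning_params: mu0 must be a positive integer")
  structure(list(r0 = r0, b = b, c = as.integer(c), mu0 = as.integer(mu0)),
            class = "tuning_params")
}

#' Hebbian inhibitory plasticity parameters
#'
#' Symmetric spike-timing rule: coincident pre/post spikes potentiate, a
#' presynaptic spike alone depresses by `eta_H * alpha_H`.  The implied
#' homeostatic firing-rate setpoint is `alpha_H / (2 * tau_STDP)` (5 Hz at
#' the defaults); see [hebbian_fixed_point()].
#'
#' @param eta_H learning rate (per spike event)
#' @param alpha_H depression bias (dimensionless)
#' @param tau_STDP trace time constant (ms)
#' @return object of class `hebbian_params`
#' @export
hebbian_params <- function(eta_H = 1e-3, alpha_H = 0.2, tau_STDP = 20) {
  if (eta_H <= 0) stop("hebbian_params: eta_H must be > 0")
  if (alpha_H < 0) stop("hebbian_params: alpha_H must be >= 0")
  if (tau_STDP <= 0) stop("hebbian_params: tau_STDP must be > 0")
  structure(list(eta_H = eta_H, alpha_H = alpha_H, tau_STDP = tau_STDP),
            class = "hebbian_params")
}

#' Homeostatic synaptic-scaling parameters
#'
#' Population-wide rule driven by a slow running estimate `y_post` (Hz) of
#' the postsynaptic rate: additive potentiation of all synapses when
#' `y_post > alpha_s * rho_0`, multiplicative depression when
#' `y_post < rho_0 / alpha_s`, and no change inside the dead zone.
#'
#' `eta_s` is a per-integration-step rate, referred to the canonical
#' 0.1 ms grid (`dt_ref`): a step of length `dt` applies the increment
#' scaled by `dt / dt_ref`.  This convention is what lets the rule collapse
#' an initially dispersed weight population within a 30 min session.
#'
#' @param eta_s learning rate (per 0.1 ms step, per Hz of rate error)
#' @param w_Is reference weight for additive potentiation
#' @param rho_0 target rate (Hz)
#' @param alpha_s dead-zone factor (> 1); no change while
#'   `rho_0/alpha_s <= y_post <= alpha_s*rho_0`
#' @param tau_scaling rate-estimator time constant (ms)
#' @param dt_ref reference step (ms) defining the units of `eta_s`
#' @return object of class `scaling_params`
#' @export
scaling_params <- function(eta_s = 1e-7, w_Is = 0.8, rho_0 = 5, alpha_s = 2,
                           tau_scaling = 1000, dt_ref = 0.1) {
  if (eta_s <= 0) stop("scaling_params: eta_s must be > 0")
  if (alpha_s <= 1) stop("scaling_params: alpha_s must be > 1 so a dead zone exists")
  if (tau_scaling <= 0 || dt_ref <= 0)
    stop("scaling_params: tau_scaling and dt_ref must be > 0")
  if (rho_0 < 0 || w_Is < 0) stop("scaling_params: rho_0 and w_Is must be >= 0")
  structure(list(eta_s = eta_s, w_Is = w_Is, rho_0 = rho_0, alpha_s = alpha_s,
                 tau_scaling = tau_scaling, dt_ref = dt_ref),
            class = "scaling_params")
}

#' Anti-Hebbian inhibitory plasticity parameters
#'
#' Sign-flipped mirror of the Hebbian rule (coincidence depresses, a lone
#' presynaptic spike potentiates by `eta_aH(t) * alpha_aH`) with a learning
#' rate that decays exponentially from `eta_aH_star` with time constant
#' `tau_aH` after onset `t0`, freezing the (otherwise unstable) rule.
#'
#' @param eta_aH_star initial learning rate
#' @param tau_aH learning-rate decay time constant (ms)
#' @param alpha_aH potentiation bias
#' @param t0 plasticity onset time (ms)
#' @param tau_STDP trace time constant (ms)
#' @return object of class `antihebbian_params`
#' @export
antihebbian_params <- function(eta_aH_star = 1e-3, tau_aH = 250e3,
                               alpha_aH = 0.165, t0 = 0, tau_STDP = 20) {
  if (eta_aH_star <= 0) stop("antihebbian_params: eta_aH_star must be > 0")
  if (tau_aH <= 0) stop("antihebbian_params: tau_aH must be > 0")
  if (tau_STDP <= 0) stop("antihebbian_params: tau_STDP must be > 0")
  structure(list(eta_aH_star = eta_aH_star, tau_aH = tau_aH,
                 alpha_aH = alpha_aH, t0 = t0, tau_STDP = tau_STDP),
            class = "antihebbian_params")
}

#' Anti-Hebbian learning rate at time t
#'
#' `eta_aH(t) = eta_aH_star * exp(-(t - t0)/tau_aH)` for `t >= t0`, 0 before.
#'
#' @param t time (ms), vectorised
#' @param params [antihebbian_params()]
#' @return learning rate(s)
#' @export
antihebbian_rate <- function(t, params = antihebbian_params()) {
  ifelse(t < params$t0, 0,
         params$eta_aH_star * exp(-(t - params$t0) / params$tau_aH))
}

#' Response-filter parameters
#'
#' Time constants of the leaky integrators used for input/output
#' correlations: `tau_Z` filters each group's pooled excitatory spike
#' train, `tau_Y` filters the postsynaptic spike train.
#'
#' @param tau_Z input filter time constant (ms)
#' @param tau_Y output filter time constant (ms)
#' @return object of class `filter_params`
#' @export
filter_params <- function(tau_Z = 10, tau_Y = 250) {
  if (tau_Z <= 0 || tau_Y <= 0) stop("filter_params: time constants must be > 0")
  structure(list(tau_Z = tau_Z, tau_Y = tau_Y), class = "filter_params")
}
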