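#' Decay spike traces over one step
#'
#' Traces decay by the exact exponential factor `exp(-dt / tau_STDP)` per
#' step (not the Euler factor), which makes the online trace agree with the
#' closed-form sum of exponentials to machine precision on grid-aligned
#' spike trains.
#'
#' @param x trace value(s)
#' @param dt elapsed time (ms)
#' @param tau_STDP trace time constant (ms)
#' @return decayed trace value(s)
#' @export
decay_traces <- function(x, dt, tau_STDP = 20) {
  x * exp(-dt / tau_STDP)
}

#' Online spike trace sampled on a time grid
#'
#' Steps through a `dt` grid, decaying by `exp(-dt/tau)` and adding +1 at
#' each (grid-aligned) spike; the trace is evaluated after the increment.
#'
#' @param spike_times spike times (ms), multiples of `dt`
#' @param duration total time (ms)
#' @param dt step (ms)
#' @param tau_STDP trace time constant (ms)
#' @return numeric vector of the trace at `dt, 2*dt, ..., duration`
#' @export
trace_online <- function(spike_times, duration, dt = 0.1, tau_STDP = 20) {
  n <- round(duration / dt)
  spk <- integer(n)
  if (length(spike_times)) {
    idx <- round(spike_times / dt)
    idx <- idx[idx >= 1 & idx <= n]
    tb <- tabulate(idx, nbins = n)
    spk <- tb
  }
  d <- exp(-dt / tau_STDP)
  x <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    cur <- cur * d + spk[i]
    x[i] <- cur
  }
  x
}

#' Closed-form spike trace (brute-force oracle)
#'
#' `x(t) = sum_k exp(-(t - t_k)/tau)` over spikes with `t_k <= t`.
#'
#' @param t evaluation time(s) (ms)
#' @param spike_times spike times (ms)
#' @param tau_STDP trace time constant (ms)
#' @return trace value(s)
#' @export
trace_closed_form <- function(t, spike_times, tau_STDP = 20) {
  vapply(t, function(ti) {
    past <- spike_times[spike_times <= ti]
    sum(exp(-(ti - past) / tau_STDP))
  }, numeric(1))
}

#' Hebbian update on a presynaptic spike
#'
#' `w <- max(0, w + eta_H * (x_post - alpha_H))`: potentiation proportional
#' to the postsynaptic trace, minus the fixed depression bias.  Trace
#' values are read before the current spike's own +1 increment.
#'
#' @param w synaptic weight(s)
#' @param x_post postsynaptic trace value
#' @param params a [hebbian_params()]
#' @return updated weight(s)
#' @export
hebbian_on_pre <- function(w, x_post, params = hebbian_params()) {
  pmax(0, w + params$eta_H * (x_post - params$alpha_H))
}

#' Hebbian update on a postsynaptic spike
#'
#' `w <- w + eta_H * x_pre`, applied to every synapse of the Hebbian
#' population (always a non-negative increment).
#'
#' @param w synaptic weight(s)
#' @param x_pre presynaptic trace value(s)
#' @param params a [hebbian_params()]
#' @return updated weight(s)
#' @export
hebbian_on_post <- function(w, x_pre, params = hebbian_params()) {
  w + params$eta_H * x_pre
}

#' Anti-Hebbian update on a presynaptic spike
#'
#' Sign-flipped mirror of the Hebbian rule with time-varying learning rate:
#' `w <- max(0, w - eta_aH(t) * (x_post - alpha_aH))`.
#'
#' @param w synaptic weight(s)
#' @param x_post postsynaptic trace value
#' @param t current time (ms), used to evaluate the decaying learning rate
#' @param params an [antihebbian_params()]
#' @return updated weight(s)
#' @export
antihebbian_on_pre <- function(w, x_post, t, params = antihebbian_params()) {
  pmax(0, w - antihebbian_rate(t, params) * (x_post - params$alpha_aH))
}

#' Anti-Hebbian update on a postsynaptic spike
#'
#' `w <- max(0, w - eta_aH(t) * x_pre)` for every synapse of the
#' anti-Hebbian population.
#'
#' @param w synaptic weight(s)
#' @param x_pre presynaptic trace value(s)
#' @param t current time (ms)
#' @param params an [antihebbian_params()]
#' @return updated weight(s)
#' @export
antihebbian_on_post <- function(w, x_pre, t, params = antihebbian_params()) {
  pmax(0, w - antihebbian_rate(t, params) * x_pre)
}

#' One step of the homeostatic scaling rule
#'
#' Updates the slow rate estimate and, outside the dead zone
#' `[rho_0/alpha_s, alpha_s*rho_0]`, the whole weight population:
#' additively (`+ eta_s * w_Is * (y_post - rho_0)`) above the zone,
#' multiplicatively (`- eta_s * w * (rho_0 - y_post)`) below it.  The
#' per-step increment is scaled by `dt / dt_ref` (see [scaling_params()]
#' for the unit convention).
#'
#' The rate estimate decays with `tau_scaling` and jumps by
#' `1000 / tau_scaling` Hz per postsynaptic spike, so its stationary mean
#' equals the postsynaptic rate in Hz.
#'
#' @param w weight vector of the scaling population
#' @param y_post current rate estimate (Hz)
#' @param post_spiked logical: did the postsynaptic neuron spike this step?
#' @param dt step (ms)
#' @param params a [scaling_params()]
#' @return list with updated `w` and `y_post`
#' @export
scaling_step <- function(w, y_post, post_spiked, dt = 0.1,
                         params = scaling_params()) {
  y_post <- y_post * exp(-dt / params$tau_scaling) +
    if (isTRUE(post_spiked)) 1000 / params$tau_scaling else 0
  eff <- params$eta_s * dt / params$dt_ref
  if (y_post > params$alpha_s * params$rho_0) {
    w <- w + eff * params$w_Is * (y_post - params$rho_0)
  } else if (y_post < params$rho_0 / params$alpha_s) {
    w <- w - eff * w * (params$rho_0 - y_post)
  }
  list(w = pmax(w, 0), y_post = y_post)
}
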