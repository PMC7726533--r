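#' One Euler step of the conductance-based LIF neuron (reference
#' implementation)
#'
#' The fixed per-step order is: (1) conductances decay by the Euler factor
#' `(1 - dt/tau_X)`, (2) this step's presynaptic weight increments are
#' added, (3) the voltage advances by one Euler step using the new
#' conductances, (4) the threshold is tested.  On a threshold crossing the
#' voltage is reset and clamped at `u_reset` for the refractory period,
#' during which the conductances keep evolving but the voltage is not
#' integrated.
#'
#' This pure-R step is the reference route for the C++ kernel; both
#' implement the identical discrete scheme.
#'
#' @param state list with `u`, `g_E`, `g_I`, `refractory_remaining`, `t`
#'   (ms); see [lif_state()]
#' @param params a [neuron_params()]
#' @param dg_E summed excitatory weight increments arriving this step
#' @param dg_I summed inhibitory weight increments arriving this step
#' @return list with the updated `state` and logical `spiked`
#' @export
lif_step <- function(state, params, dg_E = 0, dg_I = 0) {
  p <- params
  g_E <- state$g_E * (1 - p$dt / p$tau_E) + dg_E
  g_I <- state$g_I * (1 - p$dt / p$tau_I) + dg_I
  spiked <- FALSE
  # the half-step tolerance keeps the clamp count exact under floating-point
  # accumulation of dt decrements
  if (state$refractory_remaining > p$dt / 2) {
    u <- p$u_reset
    refr <- max(0, state$refractory_remaining - p$dt)
  } else {
    u <- state$u + (p$dt / p$tau_m) *
      (-(state$u - p$u_rest) - g_E * (state$u - p$E_E) - g_I * (state$u - p$E_I))
    refr <- 0
    if (u >= p$u_th) {
      spiked <- TRUE
      u <- p$u_reset
      refr <- p$tau_ref
    }
  }
  if (!all(is.finite(c(u, g_E, g_I)))) {
    bad <- c("membrane potential u", "conductance g_E", "conductance g_I")
    stop("integration failure: non-finite ",
         paste(bad[!is.finite(c(u, g_E, g_I))], collapse = ", "),
         " at t = ", state$t + p$dt, " ms")
  }
  list(state = list(u = u, g_E = g_E, g_I = g_I,
                    refractory_remaining = refr, t = state$t + p$dt),
       spiked = spiked)
}

#' Initial LIF state
#'
#' @param params a [neuron_params()]
#' @param u initial voltage (defaults to rest)
#' @return state list for [lif_step()]
#' @export
lif_state <- function(params = neuron_params(), u = params$u_rest) {
  list(u = u, g_E = 0, g_I = 0, refractory_remaining = 0, t = 0)
}

#' Run the LIF neuron over a fixed presynaptic raster (reference
#' implementation)
#'
#' Pure-R integration loop over a precomputed spike raster, suitable for
#' short desk-scale runs and for step-by-step comparison against the C++
#' kernel.  No plasticity; weights are fixed.
#'
#' @param params a [neuron_params()]
#' @param weights weight vector over afferents
#' @param pop population map (0 excitatory, > 0 inhibitory), same length
#' @param raster list with `time` (ms) and `afferent` (indices); spike
#'   times are assigned to steps by `ceiling(time/dt)`
#' @param duration total time (ms)
#' @param record_trace logical: keep per-step voltage/conductance traces?
#' @return list with `spikes` (postsynaptic spike times, ms), and if
#'   requested `trace` (data.frame t, u, g_E, g_I)
#' @export
run_lif_r <- function(params, weights, pop, raster, duration,
                      record_trace = FALSE) {
  n_steps <- round(duration / params$dt)
  step_of <- pmin(pmax(ceiling(raster$time / params$dt), 1L), n_steps)
  exc <- pop[raster$afferent] == 0L
  dgE <- numeric(n_steps)
  dgI <- numeric(n_steps)
  if (length(step_of)) {
    dgE_add <- tapply(weights[raster$afferent[exc]], step_of[exc], sum)
    dgE[as.integer(names(dgE_add))] <- dgE_add
    dgI_add <- tapply(weights[raster$afferent[!exc]], step_of[!exc], sum)
    if (length(dgI_add)) dgI[as.integer(names(dgI_add))] <- dgI_add
  }
  st <- lif_state(params)
  spikes <- numeric(0)
  tr_u <- tr_ge <- tr_gi <- if (record_trace) numeric(n_steps) else NULL
  for (s in seq_len(n_steps)) {
    res <- lif_step(st, params, dgE[s], dgI[s])
    st <- res$state
    if (res$spiked) spikes <- c(spikes, s * params$dt)
    if (record_trace) {
      tr_u[s] <- st$u; tr_ge[s] <- st$g_E; tr_gi[s] <- st$g_I
    }
  }
  out <- list(spikes = spikes, duration = duration)
  if (record_trace)
    out$trace <- data.frame(t = seq_len(n_steps) * params$dt,
                            u = tr_u, g_E = tr_ge, g_I = tr_gi)
  out
}
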