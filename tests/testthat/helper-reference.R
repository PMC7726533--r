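# Full pure-R reference simulator for raster input with online plasticity:
# an independent re-implementation of the discrete scheme (same fixed order
# of operations) used to validate the C++ kernel step for step.
run_ref_plastic <- function(model, raster, duration, plasticity = TRUE) {
  p <- model$neuron
  arch <- model$arch
  dt <- p$dt
  n_steps <- round(duration / dt)
  w <- model$weights
  rule <- c(fixed = 0L, hebbian = 1L, scaling = 2L,
            anti_hebbian = 3L)[model$rules]
  hb <- model$hebbian; sc <- model$scaling; ah <- model$antihebbian
  step_of <- pmin(pmax(ceiling(raster$time / dt), 1L), n_steps)
  ev_by_step <- split(raster$afferent[order(step_of, raster$afferent)],
                      sort(step_of))
  d_stdp <- exp(-dt / hb$tau_STDP)
  d_sc <- exp(-dt / sc$tau_scaling)
  x_pre <- numeric(arch$n); x_post <- 0
  y_post <- sc$rho_0
  u <- p$u_rest; g_E <- 0; g_I <- 0; refr <- 0
  spikes <- numeric(0)
  eta_eff <- sc$eta_s / sc$dt_ref
  for (s in seq_len(n_steps)) {
    g_E <- g_E * (1 - dt / p$tau_E)
    g_I <- g_I * (1 - dt / p$tau_I)
    ev <- ev_by_step[[as.character(s)]]
    if (!is.null(ev)) {
      for (j in ev) {
        if (arch$pop[j] == 0) g_E <- g_E + w[j] else g_I <- g_I + w[j]
      }
    }
    spiked <- FALSE
    if (refr > 0) {
      refr <- refr - 1
      u <- p$u_reset
    } else {
      u <- u + (dt / p$tau_m) *
        (-(u - p$u_rest) - g_E * (u - p$E_E) - g_I * (u - p$E_I))
      if (u >= p$u_th) {
        spiked <- TRUE; u <- p$u_reset; refr <- round(p$tau_ref / dt)
        spikes <- c(spikes, s * dt)
      }
    }
    x_pre <- x_pre * d_stdp
    x_post <- x_post * d_stdp
    if (plasticity) {
      t_now <- s * dt
      eta_aH <- if (t_now < ah$t0) 0 else
        ah$eta_aH_star * exp(-(t_now - ah$t0) / ah$tau_aH)
      inh_ev <- if (is.null(ev)) integer(0) else ev[arch$pop[ev] > 0]
      for (j in inh_ev) {
        r <- rule[arch$pop[j]]
        if (r == 1L) w[j] <- max(0, w[j] + hb$eta_H * (x_post - hb$alpha_H))
        if (r == 3L) w[j] <- max(0, w[j] - eta_aH * (x_post - ah$alpha_aH))
      }
      if (spiked) {
        for (i in seq_along(rule)) {
          mem <- which(arch$pop == i)
          if (rule[i] == 1L) w[mem] <- w[mem] + hb$eta_H * x_pre[mem]
          if (rule[i] == 3L) w[mem] <- pmax(0, w[mem] - eta_aH * x_pre[mem])
        }
      }
      if (any(rule == 2L)) {
        y_post <- y_post * d_sc + if (spiked) 1000 / sc$tau_scaling else 0
        mem <- which(arch$pop %in% which(rule == 2L))
        if (y_post > sc$alpha_s * sc$rho_0) {
          w[mem] <- w[mem] + eta_eff * dt * sc$w_Is * (y_post - sc$rho_0)
        } else if (y_post < sc$rho_0 / sc$alpha_s) {
          w[mem] <- pmax(0, w[mem] - eta_eff * dt * w[mem] * (sc$rho_0 - y_post))
        }
      }
    }
    if (!is.null(ev)) x_pre[ev] <- x_pre[ev] + 1
    if (spiked) x_post <- x_post + 1
  }
  list(spikes = spikes, w = w, y_post = y_post)
}
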