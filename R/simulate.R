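#' Simulate a session of the model
#'
#' Runs the closed-loop simulation for `duration` ms: input spike trains
#' are generated on the fly (OU-modulated natural input, a pulse protocol,
#' or a user-supplied raster), the LIF neuron is integrated on the `dt`
#' grid, bound plasticity rules are applied online when `plasticity =
#' TRUE`, and input/output correlation filters are accumulated after a
#' burn-in.  Identical arguments and seed give bit-identical results.
#'
#' @param model an [isp_model()]
#' @param duration session length (ms)
#' @param input `"natural"`, `"pulse"`, or `"raster"`
#' @param gains inhibitory gain per population (1 = control, 0 = inactive)
#' @param plasticity apply the bound plasticity rules?
#' @param pulse a [pulse_params()] (for `input = "pulse"`); the pulse
#'   starts at `pulse_onset`
#' @param pulse_onset pulse onset time (ms)
#' @param raster list with `time` and `afferent` (for `input = "raster"`)
#' @param seed RNG seed; the session is deterministic given the seed
#' @param correlation accumulate per-group input/output correlations?
#' @param trace_stride record voltage/conductance every this many steps
#'   (0 = off)
#' @param weights_every record full weight snapshots every this many ms
#'   (0 = off)
#' @param record_input_spikes keep the generated input raster (memory-heavy;
#'   desk-scale runs only)
#' @param burn_in transient discarded before correlation accumulation (ms);
#'   defaults to the model's metric settings
#' @return object of class `isp_session`: postsynaptic `spikes` (ms),
#'   `rate` (list mean/sd in Hz), `cv_isi`, per-group correlations `C`,
#'   performance index `delta_C`, final `weights`, and any requested
#'   recordings
#' @export
simulate_session <- function(model, duration, input = c("natural", "pulse", "raster"),
                             gains = rep(1, model$arch$n_inh_pops),
                             plasticity = FALSE, pulse = NULL, pulse_onset = 0,
                             raster = NULL, seed = NULL, correlation = TRUE,
                             trace_stride = 0, weights_every = 0,
                             record_input_spikes = FALSE, burn_in = NULL) {
  input <- match.arg(input)
  stopifnot(inherits(model, "isp_model"))
  if (duration <= 0) stop("simulate_session: duration must be > 0")
  dt <- model$neuron$dt
  if (abs(duration / dt - round(duration / dt)) > 1e-9)
    stop("simulate_session: duration must be a multiple of dt")
  gains <- rep_len(gains, model$arch$n_inh_pops)
  if (any(gains < 0)) stop("simulate_session: gains must be >= 0")
  if (is.null(burn_in)) burn_in <- if (duration > 4 * model$burn_in) model$burn_in else 0

  in_list <- list(gains = gains)
  if (input == "natural") {
    r <- model$rates
    in_list <- c(in_list, list(dT = r$dT, tau_OU = r$tau_OU, nu_E0 = r$nu_E0,
                               nu_I0 = r$nu_I0, nu_Ebg = r$nu_Ebg,
                               nu_Ibg = r$nu_Ibg, tau_Eref = r$tau_Eref,
                               tau_Iref = r$tau_Iref))
  } else if (input == "pulse") {
    if (is.null(pulse)) pulse <- pulse_params()
    r <- model$rates
    in_list <- c(in_list, list(dT = r$dT, nu_Ebg = r$nu_Ebg, nu_Ibg = r$nu_Ibg,
                               tau_Eref = r$tau_Eref, tau_Iref = r$tau_Iref,
                               onset = pulse_onset, pulse_duration = pulse$duration,
                               target_group = pulse$target_group, k = pulse$k,
                               nu_star = pulse$nu_star, alpha_E = pulse$alpha_E,
                               alpha_I = pulse$alpha_I))
    if (pulse$target_group > model$arch$n_groups)
      stop("simulate_session: pulse target group out of range")
  } else {
    if (is.null(raster)) stop("simulate_session: raster input requires 'raster'")
    step <- as.integer(pmin(pmax(ceiling(raster$time / dt), 1L),
                            round(duration / dt)))
    o <- order(step, raster$afferent)
    in_list <- c(in_list, list(step = step[o],
                               afferent = as.integer(raster$afferent[o])))
  }

  plast <- list(
    enabled = isTRUE(plasticity),
    rule = rule_code(model$rules),
    tau_STDP = model$hebbian$tau_STDP,
    eta_H = model$hebbian$eta_H, alpha_H = model$hebbian$alpha_H,
    eta_s_eff = model$scaling$eta_s / model$scaling$dt_ref,
    w_Is = model$scaling$w_Is, rho_0 = model$scaling$rho_0,
    alpha_s = model$scaling$alpha_s, tau_scaling = model$scaling$tau_scaling,
    eta_aH_star = model$antihebbian$eta_aH_star,
    tau_aH = model$antihebbian$tau_aH, alpha_aH = model$antihebbian$alpha_aH,
    t0 = model$antihebbian$t0,
    y_post0 = model$scaling$rho_0
  )
  record <- list(trace_stride = as.integer(trace_stride),
                 weights_every = weights_every,
                 input_spikes = isTRUE(record_input_spikes),
                 correlation = isTRUE(correlation),
                 tau_Z = model$metrics$tau_Z, tau_Y = model$metrics$tau_Y,
                 burn_in = burn_in)
  args <- list(neuron = unclass(model$neuron), duration = duration,
               group = model$arch$group, pop = model$arch$pop,
               n_groups = model$arch$n_groups,
               n_inh_pops = model$arch$n_inh_pops,
               w = model$weights, input_mode = input, input = in_list,
               plasticity = plast, record = record)

  res <- with_seed(seed, .cpp_simulate(args))

  rs <- rate_stats(res$spikes, duration, model$rate_bin)
  cv <- if (length(res$spikes) >= 3) cv_isi(res$spikes) else NA_real_
  C <- as.numeric(res$C)
  dC <- if (correlation && !anyNA(C[c(model$preferred, model$nonpreferred)]))
    performance_index(C, model$preferred, model$nonpreferred) else NA_real_

  structure(list(
    spikes = res$spikes, duration = duration, rate = rs, cv_isi = cv,
    C = C, delta_C = dC, weights = res$w_final, y_post = res$y_post,
    gains = gains, input = input, plasticity = isTRUE(plasticity),
    seed = seed, burn_in = burn_in,
    trace = res$trace, w_snapshots = res$w_snapshots,
    snapshot_times = res$snapshot_times, input_spikes = res$input_spikes,
    model = model
  ), class = "isp_session")
}

#' @export
print.isp_session <- function(x, ...) {
  cat(sprintf("Session: %.1f s %s input%s, gains (%s)\n",
              x$duration / 1000, x$input,
              if (x$plasticity) " with plasticity" else "",
              paste(format(x$gains), collapse = ", ")))
  cat(sprintf("  output: %d spikes, %.2f Hz (SD %.2f Hz), CV_ISI %.2f\n",
              x$rate$n_spikes, x$rate$mean, x$rate$sd, x$cv_isi))
  if (!is.na(x$delta_C))
    cat(sprintf("  performance index delta_C = %.3f (C_pref %.3f, C_nonpref %.3f)\n",
                x$delta_C, x$C[x$model$preferred], x$C[x$model$nonpreferred]))
  invisible(x)
}

#' @export
summary.isp_session <- function(object, ...) {
  out <- list(rate = object$rate, cv_isi = object$cv_isi,
              C = object$C, delta_C = object$delta_C, gains = object$gains)
  class(out) <- "summary.isp_session"
  out
}

#' @export
print.summary.isp_session <- function(x, ...) {
  cat(sprintf("mean rate %.2f Hz, SD %.2f Hz, CV_ISI %.2f\n",
              x$rate$mean, x$rate$sd, x$cv_isi))
  if (!all(is.na(x$C))) {
    cat("per-group correlation C:\n")
    print(round(x$C, 3))
    cat(sprintf("delta_C = %.3f\n", x$delta_C))
  }
  invisible(x)
}
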