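#' Build a single-neuron model with plastic inhibitory populations
#'
#' Assembles the full model: a conductance-based LIF neuron, a tuned
#' excitatory afferent population organised in signal groups, and one or
#' two inhibitory populations with a plasticity rule bound to each
#' (`"hebbian"`, `"scaling"`, `"anti_hebbian"`, or `"fixed"`).
#'
#' `scale` shrinks the model for desk-scale work: the number of signal
#' groups and every per-group afferent count are multiplied by
#' `sqrt(scale)` (so the total afferent count scales by `scale`), and the
#' fixed excitatory baseline weight is scaled up by the inverse of the
#' per-group count ratio so the total excitatory drive is preserved.
#' Inhibitory initial weights are plastic and are left at their nominal
#' values.  The preferred group index maps proportionally (9 of 16 at full
#' scale, e.g. 5 of 8 at scale 0.25) and the tuning slope `b` grows as
#' `(P_full/P_scaled)^c` so the receptive-field shape over the normalized
#' group axis — and with it the preferred/nonpreferred contrast — is
#' preserved.  `scale = 0.25` with a single
#' inhibitory population gives 8 groups x (100 excitatory + 25 inhibitory)
#' = 800 excitatory and 200 inhibitory afferents.
#'
#' @param rules character vector, one rule per inhibitory population
#' @param scale area scale factor in (0, 1]
#' @param config configuration list, see [default_config()]
#' @param seed RNG seed for the initial weight draw (noise terms)
#' @param w_IF,eps_I optional overrides of the inhibitory initial baseline
#'   and noise half-width; a scalar or one value per population.  Defaults
#'   depend on the rule combination (see [default_config()])
#' @return object of class `isp_model`
#' @export
isp_model <- function(rules = c("hebbian", "scaling"), scale = 1,
                      config = default_config(), seed = NULL,
                      w_IF = NULL, eps_I = NULL) {
  rules <- match.arg(rules, c("hebbian", "scaling", "anti_hebbian", "fixed"),
                     several.ok = TRUE)
  if (length(rules) < 1 || length(rules) > 2)
    stop("isp_model: one or two inhibitory populations are supported")
  if (scale <= 0 || scale > 1) stop("isp_model: scale must be in (0, 1]")
  validate_config(config)
  n_pops <- length(rules)

  a <- config$architecture
  f <- sqrt(scale)
  n_groups <- max(2L, as.integer(round_half_up(a$n_groups * f)))
  n_exc_pg <- max(1L, as.integer(round_half_up(a$n_exc_per_group * f)))
  n_inh_pg_full <- if (n_pops == 1) a$n_inh_per_group_single else a$n_inh_per_group
  n_inh_pg <- max(1L, as.integer(round_half_up(n_inh_pg_full * f)))
  arch <- input_architecture(n_groups, n_exc_pg, rep(n_inh_pg, n_pops), n_pops)

  mu0 <- min(n_groups, as.integer(ceiling(config$tuning$mu0 * n_groups /
                                            a$n_groups)))
  # preserve the tuning-profile shape over the normalized group axis:
  # group distances shrink by n_groups/P_full, so the slope must grow by
  # the inverse ratio to the power c (capped at the profile's b <= 1 bound)
  b_eff <- min(1, config$tuning$b * (a$n_groups / n_groups)^config$tuning$c)
  tuning <- tuning_params(config$tuning$r0, b_eff, config$tuning$c, mu0)
  w_E0_eff <- config$weights$w_E0 * a$n_exc_per_group / n_exc_pg

  # inhibitory initial conditions by rule combination unless overridden
  defaults <- if (n_pops == 1) c(0.4, 0.01)
    else if (setequal(rules, c("hebbian", "scaling"))) c(0.8, 0.3)
    else if (setequal(rules, c("hebbian", "anti_hebbian"))) c(0.55, 0.01)
    else c(0.8, 0.01)
  if (is.null(w_IF)) w_IF <- config$weights$w_IF
  if (is.null(w_IF)) w_IF <- defaults[1]
  if (is.null(eps_I)) eps_I <- config$weights$eps_I
  if (is.null(eps_I)) eps_I <- defaults[2]
  w_IF <- rep_len(w_IF, n_pops)
  eps_I <- rep_len(eps_I, n_pops)

  w <- with_seed(seed, {
    w0 <- init_excitatory_weights(arch, tuning, w_E0_eff, config$weights$eps_E)
    for (i in seq_len(n_pops))
      w0 <- w0 + init_inhibitory_weights(arch, i, w_IF[i], eps_I[i])
    w0
  })

  structure(list(
    arch = arch,
    neuron = do.call(neuron_params, config$neuron),
    rates = do.call(rate_params, config$rates),
    tuning = tuning,
    rules = rules,
    weights = w,
    hebbian = do.call(hebbian_params,
                      c(config$plasticity$hebbian,
                        list(tau_STDP = config$plasticity$tau_STDP))),
    scaling = do.call(scaling_params, config$plasticity$scaling),
    antihebbian = do.call(antihebbian_params,
                          c(config$plasticity$antihebbian,
                            list(tau_STDP = config$plasticity$tau_STDP))),
    metrics = filter_params(config$metrics$tau_Z, config$metrics$tau_Y),
    burn_in = config$metrics$burn_in,
    rate_bin = config$metrics$rate_bin,
    preferred = mu0,
    nonpreferred = 1L,
    scale = scale,
    w_IF = w_IF,
    eps_I = eps_I,
    w_E0_eff = w_E0_eff,
    config = config,
    init_seed = seed
  ), class = "isp_model")
}

#' @export
print.isp_model <- function(x, ...) {
  cat("Single-neuron model with inhibitory plasticity\n")
  print(x$arch)
  cat("  rules:", paste(seq_along(x$rules), x$rules, sep = ":",
                        collapse = ", "), "\n")
  cat(sprintf("  preferred group: %d of %d; scale %.3g\n",
              x$preferred, x$arch$n_groups, x$scale))
  invisible(x)
}

rule_code <- function(rules) {
  unname(c(fixed = 0L, hebbian = 1L, scaling = 2L, anti_hebbian = 3L)[rules])
}
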