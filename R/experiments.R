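#' Train the inhibitory weights of a model
#'
#' Runs a closed-loop natural-input session with the bound plasticity
#' rules active (default length: 30 simulated minutes times the model
#' scale) and returns the model with learned weights plus the weight
#' trajectory.  Aborts with a diagnostic on divergence (sustained output
#' above 250 Hz or non-finite state).
#'
#' @param model an [isp_model()]
#' @param duration training length (ms); default
#'   `config$experiment$train_min * 60000 * scale`
#' @param seed RNG seed for the training inputs
#' @param snapshot_every weight-snapshot cadence (ms)
#' @param gains inhibitory gains during training (control = 1)
#' @return object of class `isp_training`: the trained `model`, the
#'   training `session`, initial weights `w0`, and snapshot trajectory
#' @export
train_inhibition <- function(model, duration = NULL, seed = NULL,
                             snapshot_every = 10e3,
                             gains = rep(1, model$arch$n_inh_pops)) {
  stopifnot(inherits(model, "isp_model"))
  if (is.null(duration))
    duration <- model$config$experiment$train_min * 60e3 * model$scale
  w0 <- model$weights
  ses <- simulate_session(model, duration, input = "natural", gains = gains,
                          plasticity = TRUE, seed = seed, correlation = FALSE,
                          weights_every = snapshot_every)
  if (!all(is.finite(ses$weights)))
    stop("training diverged: non-finite weights")
  trained <- model
  trained$weights <- ses$weights
  structure(list(model = trained, session = ses, w0 = w0,
                 w_snapshots = ses$w_snapshots,
                 snapshot_times = ses$snapshot_times,
                 duration = duration, seed = seed), class = "isp_training")
}

#' @export
print.isp_training <- function(x, ...) {
  cat(sprintf("Trained model (%.1f min natural input)\n",
              x$duration / 60e3))
  cat(sprintf("  rules: %s\n", paste(x$model$rules, collapse = ", ")))
  cat(sprintf("  final output rate %.2f Hz\n", x$session$rate$mean))
  invisible(x)
}

#' @export
coef.isp_training <- function(object, ...) {
  object$model$weights
}

#' @export
summary.isp_training <- function(object, ...) {
  m <- object$model
  prof <- lapply(0:m$arch$n_inh_pops, function(p)
    group_mean_weights(m$arch, m$weights, p))
  names(prof) <- c("excitatory", paste0("inhibitory_", seq_len(m$arch$n_inh_pops)))
  out <- list(profiles = prof, rate = object$session$rate,
              rules = m$rules, duration = object$duration)
  class(out) <- "summary.isp_training"
  out
}

#' @export
print.summary.isp_training <- function(x, ...) {
  cat(sprintf("Training summary (%.1f min): final rate %.2f Hz\n",
              x$duration / 60e3, x$rate$mean))
  cat("per-group mean weight profiles:\n")
  print(round(do.call(rbind, x$profiles), 3))
  invisible(x)
}

#' Plot learned weight profiles
#'
#' Per-group mean weights of the excitatory and each inhibitory
#' population, against signal-group index.
#'
#' @param x an `isp_training`
#' @param ... passed to [graphics::matplot()]
#' @export
plot.isp_training <- function(x, ...) {
  m <- x$model
  prof <- sapply(0:m$arch$n_inh_pops, function(p)
    group_mean_weights(m$arch, m$weights, p))
  graphics::matplot(seq_len(m$arch$n_groups), prof, type = "b", pch = 16,
                    lty = 1, xlab = "signal group", ylab = "mean weight", ...)
  graphics::abline(v = m$preferred, lty = 2, col = "grey")
  graphics::legend("topleft", bty = "n",
                   legend = c("excitatory",
                              paste0("inhibitory ", seq_len(m$arch$n_inh_pops),
                                     " (", m$rules, ")")),
                   col = seq_len(m$arch$n_inh_pops + 1), pch = 16)
  invisible(x)
}

as_model <- function(x) {
  if (inherits(x, "isp_training")) x$model
  else if (inherits(x, "isp_model")) x
  else stop("expected an isp_model or isp_training")
}

#' Probe a (trained) model with plasticity frozen
#'
#' A natural-input session at the given inhibitory gains with all
#' plasticity off; weights are identical before and after.
#'
#' @param x an [isp_model()] or [train_inhibition()] result
#' @param gains inhibitory gain per population
#' @param duration probe length (ms); default
#'   `config$experiment$probe_min * 60000`
#' @param seed RNG seed (use seeds disjoint from training)
#' @param ... passed to [simulate_session()]
#' @return an `isp_session`
#' @export
probe <- function(x, gains = NULL, duration = NULL, seed = NULL, ...) {
  model <- as_model(x)
  if (is.null(gains)) gains <- rep(1, model$arch$n_inh_pops)
  if (is.null(duration)) duration <- model$config$experiment$probe_min * 60e3
  simulate_session(model, duration, input = "natural", gains = gains,
                   plasticity = FALSE, seed = seed, ...)
}

#' Sweep the gain of one inhibitory population
#'
#' Re-runs frozen-weight probes over a grid of rate gains for one
#' population (the other population, if any, stays at `other_gain`) and
#' tabulates rate statistics and the performance index.
#'
#' @param x model or training result
#' @param pop population whose gain is swept
#' @param gains gain grid (1 = control)
#' @param other_gain gain of the non-swept population
#' @param duration probe length (ms)
#' @param seed base seed; probe i uses `seed + i`
#' @return list with `table` (data.frame gain, rate_mean, rate_sd, cv_isi,
#'   C_pref, C_nonpref, delta_C) and `sessions`
#' @export
gain_sweep <- function(x, pop = 1L, gains = seq(0.5, 1.5, by = 0.05),
                       other_gain = 1, duration = NULL, seed = NULL) {
  model <- as_model(x)
  sessions <- vector("list", length(gains))
  rows <- vector("list", length(gains))
  for (i in seq_along(gains)) {
    g <- rep(other_gain, model$arch$n_inh_pops)
    g[pop] <- gains[i]
    s <- probe(model, gains = g, duration = duration,
               seed = if (is.null(seed)) NULL else seed + i)
    sessions[[i]] <- s
    rows[[i]] <- data.frame(gain = gains[i], rate_mean = s$rate$mean,
                            rate_sd = s$rate$sd, cv_isi = s$cv_isi,
                            C_pref = s$C[model$preferred],
                            C_nonpref = s$C[model$nonpreferred],
                            delta_C = s$delta_C)
  }
  list(table = do.call(rbind, rows), sessions = sessions)
}

#' Find the compensatory gain that restores the target output rate
#'
#' With one inhibitory population inactive (gain 0), searches the gain of
#' the remaining population by bisection until the mean output rate over a
#' probe matches the target within tolerance.  The output rate decreases
#' monotonically with inhibitory gain, which is checked on the initial
#' bracket.
#'
#' @param x model or training result (two inhibitory populations)
#' @param off_pop population to silence (gain 0)
#' @param target target output rate (Hz); defaults to the plasticity
#'   setpoint `rho_0`
#' @param tol rate tolerance (Hz)
#' @param bracket gain search interval
#' @param duration probe length per evaluation (ms)
#' @param seed base seed; evaluation i uses `seed + i`
#' @param max_iter bisection iteration cap
#' @return list with `gain`, `rate` (achieved), `off_pop`, `n_eval`
#' @export
compensatory_gain <- function(x, off_pop, target = NULL, tol = NULL,
                              bracket = NULL, duration = NULL, seed = NULL,
                              max_iter = 12L) {
  model <- as_model(x)
  if (model$arch$n_inh_pops < 2)
    stop("compensatory_gain: needs two inhibitory populations")
  if (is.null(target)) target <- model$scaling$rho_0
  if (is.null(tol)) tol <- model$config$experiment$compensate_tol
  if (is.null(bracket)) bracket <- model$config$experiment$compensate_bracket
  on_pop <- setdiff(seq_len(model$arch$n_inh_pops), off_pop)[1]
  n_eval <- 0L
  rate_at <- function(g) {
    n_eval <<- n_eval + 1L
    gains <- numeric(model$arch$n_inh_pops)
    gains[off_pop] <- 0
    gains[on_pop] <- g
    probe(model, gains = gains, duration = duration,
          seed = if (is.null(seed)) NULL else seed + n_eval,
          correlation = FALSE)$rate$mean
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- rate_at(lo); r_hi <- rate_at(hi)
  if (r_lo < r_hi)
    stop("compensatory_gain: output rate does not decrease with gain on the bracket")
  if (target > r_lo + tol || target < r_hi - tol)
    stop(sprintf(paste0("compensatory_gain: target %.2f Hz not bracketed in ",
                        "[%.2f, %.2f] (rates %.2f..%.2f Hz)"),
                 target, lo, hi, r_hi, r_lo))
  g <- (lo + hi) / 2; r <- NA_real_
  for (i in seq_len(max_iter)) {
    g <- (lo + hi) / 2
    r <- rate_at(g)
    if (abs(r - target) <= tol) break
    if (r > target) lo <- g else hi <- g
  }
  list(gain = g, rate = r, off_pop = off_pop, on_pop = on_pop, n_eval = n_eval)
}

#' Pulse-response sweep
#'
#' For each stimulated signal group and each pulse amplitude `k`, runs
#' `trials` frozen-weight pulse trials plus matched background-only
#' (`k = 0`) trials, and returns baseline-subtracted phasic (first 50 ms)
#' and tonic (last 50 ms) responses in Hz.
#'
#' @param x model or training result
#' @param k_values integer pulse amplitudes (in units of `nu_star`)
#' @param groups signal groups to stimulate (default: all)
#' @param trials trials per (group, k)
#' @param gains inhibitory gain per population
#' @param seed base seed; trials use consecutive seeds
#' @param settle pre-pulse settling time (ms)
#' @return list with matrices `phasic` and `tonic` (group x k, Hz), the
#'   baseline mean counts, and the call parameters
#' @export
pulse_sweep <- function(x, k_values = c(2, 4, 8), groups = NULL, trials = 100,
                        gains = NULL, seed = NULL, settle = NULL) {
  model <- as_model(x)
  if (is.null(groups)) groups <- seq_len(model$arch$n_groups)
  if (is.null(gains)) gains <- rep(1, model$arch$n_inh_pops)
  if (is.null(settle)) settle <- model$config$experiment$pulse_settle
  pp <- model$config$pulse
  half <- pp$duration / 2
  trial_counts <- function(k, g, seed_off) {
    ph <- numeric(trials); tn <- numeric(trials)
    for (tr in seq_len(trials)) {
      ps <- pulse_params(nu_star = pp$nu_star, k = k, alpha_E = pp$alpha_E,
                         alpha_I = pp$alpha_I, duration = pp$duration,
                         target_group = g)
      s <- simulate_session(model, settle + pp$duration, input = "pulse",
                            gains = gains, pulse = ps, pulse_onset = settle,
                            seed = if (is.null(seed)) NULL else seed + seed_off + tr,
                            correlation = FALSE)
      ph[tr] <- sum(s$spikes > settle & s$spikes <= settle + half)
      tn[tr] <- sum(s$spikes > settle + half & s$spikes <= settle + pp$duration)
    }
    cbind(ph, tn)
  }
  base <- trial_counts(0, 1L, 0L)
  phasic <- matrix(NA_real_, length(groups), length(k_values),
                   dimnames = list(group = groups, k = k_values))
  tonic <- phasic
  off <- trials
  for (gi in seq_along(groups)) {
    for (ki in seq_along(k_values)) {
      k <- k_values[ki]
      if (k == 0) {
        phasic[gi, ki] <- 0; tonic[gi, ki] <- 0
        next
      }
      ct <- trial_counts(k, groups[gi], off)
      off <- off + trials
      phasic[gi, ki] <- pulse_response(ct[, 1], base[, 1])
      tonic[gi, ki] <- pulse_response(ct[, 2], base[, 2])
    }
  }
  list(phasic = phasic, tonic = tonic,
       baseline = colMeans(base), k_values = k_values, groups = groups,
       trials = trials, gains = gains)
}

#' Reproduce a named experiment protocol
#'
#' Orchestrates the package's standard protocols at a chosen scale and
#' returns plain data tables.  Supported protocols:
#' \describe{
#'   \item{`fixed_partner`}{Hebbian plasticity in population 1 against a
#'     fixed population 2, over a set of initial weights for the fixed
#'     population: final rates and weight profiles.}
#'   \item{`hebbian_scaling`}{co-training of Hebbian + scaling
#'     populations: weight profiles and scaling-population collapse.}
#'   \item{`hebbian_antihebbian`}{co-training of Hebbian + anti-Hebbian
#'     populations.}
#'   \item{`switching`}{performance-index table (control, population 1
#'     off, population 2 off, with compensatory gain) for a trained
#'     Hebbian + scaling model.}
#' }
#'
#' @param protocol protocol name
#' @param scale model scale
#' @param seed base seed
#' @param train_duration,probe_duration overrides (ms)
#' @param w_if_values initial fixed-population weights (`fixed_partner`)
#' @param config configuration list
#' @return a list of result tables (protocol-specific)
#' @export
reproduce_protocol <- function(protocol = c("fixed_partner", "hebbian_scaling",
                                            "hebbian_antihebbian", "switching"),
                               scale = 0.25, seed = 1,
                               train_duration = NULL, probe_duration = NULL,
                               w_if_values = c(0.2, 0.6, 1.0, 1.4),
                               config = default_config()) {
  protocol <- match.arg(protocol)
  if (protocol == "fixed_partner") {
    rows <- list(); profiles <- list()
    for (i in seq_along(w_if_values)) {
      m <- isp_model(c("hebbian", "fixed"), scale = scale, config = config,
                     seed = seed + i, w_IF = c(0.4, w_if_values[i]))
      tr <- train_inhibition(m, duration = train_duration, seed = seed + 100 + i)
      last_min <- tr$session$spikes[tr$session$spikes > tr$duration - 60e3]
      prof1 <- group_mean_weights(m$arch, tr$model$weights, 1)
      prof2 <- group_mean_weights(m$arch, tr$model$weights, 2)
      rows[[i]] <- data.frame(w_if_fixed = w_if_values[i],
                              final_rate = length(last_min) / 60,
                              plastic_weight_sum = sum(prof1),
                              total_inh_weight = sum(prof1 + prof2))
      profiles[[i]] <- cbind(plastic = prof1, fixed = prof2)
    }
    return(list(table = do.call(rbind, rows), profiles = profiles))
  }
  rules <- switch(protocol,
                  hebbian_scaling = c("hebbian", "scaling"),
                  hebbian_antihebbian = c("hebbian", "anti_hebbian"),
                  switching = c("hebbian", "scaling"))
  m <- isp_model(rules, scale = scale, config = config, seed = seed)
  tr <- train_inhibition(m, duration = train_duration, seed = seed + 100)
  prof <- sapply(0:2, function(p) group_mean_weights(m$arch, tr$model$weights, p))
  colnames(prof) <- c("excitatory", rules)
  if (protocol != "switching") {
    w2 <- tr$model$weights[m$arch$pop == 2]
    return(list(profiles = prof, final_rate = tr$session$rate$mean,
                pop2_cv = stats::sd(w2) / mean(w2)))
  }
  ctrl <- probe(tr, duration = probe_duration, seed = seed + 200)
  res <- list(control = ctrl$delta_C)
  for (off in 1:2) {
    cg <- compensatory_gain(tr, off_pop = off, duration = probe_duration,
                            seed = seed + 300 * off)
    gains <- numeric(2); gains[off] <- 0; gains[cg$on_pop] <- cg$gain
    s <- probe(tr, gains = gains, duration = probe_duration,
               seed = seed + 400 + off)
    res[[paste0("pop", off, "_off")]] <- s$delta_C
  }
  list(profiles = prof, delta_C = unlist(res))
}
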