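#' One update of the rate-modulating OU process
#'
#' The latent variable of each signal group evolves on a `dT` grid as
#' `y <- y + dT * (-y / tau_OU) + xi`, with `xi` a standard-normal draw per
#' update (unit SD per update, not per sqrt-time; see the methods
#' vignette).  The stationary distribution has mean 0 and SD close to
#' `sqrt(tau_OU / (2 * dT))`, so with the defaults the rectified variable
#' drives active-period rates of tens of Hz.
#'
#' @param y current value(s), one per signal group
#' @param tau_OU OU time constant (ms)
#' @param dT update step (ms)
#' @param xi optional noise draw(s); defaults to `rnorm(length(y))`
#' @return updated y
#' @export
ou_step <- function(y, tau_OU = 50, dT = 1, xi = NULL) {
  if (is.null(xi)) xi <- stats::rnorm(length(y))
  y + dT * (-y / tau_OU) + xi
}

#' Stationary SD of the discrete OU process
#' @param tau_OU OU time constant (ms)
#' @param dT update step (ms)
#' @return stationary standard deviation of y
#' @export
ou_stationary_sd <- function(tau_OU = 50, dT = 1) {
  a <- 1 - dT / tau_OU
  sqrt(1 / (1 - a^2))
}

#' Simulate an OU trajectory on the dT grid
#'
#' @param n_steps number of updates
#' @param tau_OU,dT as in [ou_step()]
#' @param y0 initial value; `NULL` draws from the stationary distribution
#' @return numeric vector of length `n_steps` (values after each update)
#' @export
ou_series <- function(n_steps, tau_OU = 50, dT = 1, y0 = NULL) {
  if (is.null(y0)) y0 <- stats::rnorm(1, 0, ou_stationary_sd(tau_OU, dT))
  a <- 1 - dT / tau_OU
  xi <- stats::rnorm(n_steps)
  y <- numeric(n_steps)
  prev <- y0
  for (i in seq_len(n_steps)) {
    prev <- a * prev + xi[i]
    y[i] <- prev
  }
  y
}

#' Instantaneous group firing rate under natural input
#'
#' `nu = gain * (nu_X0 * max(y, 0) + nu_Xbg)` where X is the population
#' class.  Excitatory afferents always have gain 1; inhibitory gains are
#' the modulation handle (0 = population inactive).
#'
#' @param y latent OU value(s)
#' @param pop `"exc"` or `"inh"`
#' @param params a [rate_params()]
#' @param gain rate multiplier (inhibitory modulation)
#' @return rate(s) in Hz
#' @export
group_rate <- function(y, pop = c("exc", "inh"), params = rate_params(),
                       gain = 1) {
  pop <- match.arg(pop)
  base <- if (pop == "exc") params$nu_E0 * pmax(y, 0) + params$nu_Ebg
          else params$nu_I0 * pmax(y, 0) + params$nu_Ibg
  if (pop == "exc") base else gain * base
}

#' Group firing rate under pulse input
#'
#' Inside the pulse window the target group fires at
#' `alpha_X * k * nu_star + nu_Xbg`; outside the window, and for all other
#' groups, the rate is the background `nu_Xbg`.
#'
#' @param t time (ms), vectorised
#' @param group signal group of the afferent
#' @param pop `"exc"` or `"inh"`
#' @param pulse a [pulse_params()]
#' @param base a [rate_params()] supplying the background rates
#' @param onset pulse onset time (ms)
#' @param gain inhibitory gain multiplier
#' @return rate(s) in Hz
#' @export
pulse_rate <- function(t, group, pop = c("exc", "inh"), pulse = pulse_params(),
                       base = rate_params(), onset = 0, gain = 1) {
  pop <- match.arg(pop)
  bg <- if (pop == "exc") base$nu_Ebg else base$nu_Ibg
  alpha <- if (pop == "exc") pulse$alpha_E else pulse$alpha_I
  amp <- alpha * pulse$k * pulse$nu_star
  in_win <- (t >= onset) & (t < onset + pulse$duration) &
    (group == pulse$target_group)
  r <- bg + ifelse(in_win, amp, 0)
  if (pop == "exc") r else gain * r
}

#' Expected afferent rate of the refractory-corrected Poisson process
#'
#' With per-step spike probability `p = nu * dt` and spiking forbidden for
#' `tau_ref` after each spike, the long-run afferent rate is
#' `F = (p / dt) * (1 - p)^(tau_ref / dt)` (Hz, for `nu` in Hz and `dt`,
#' `tau_ref` in ms).
#'
#' @param nu nominal rate (Hz)
#' @param dt time step (ms)
#' @param tau_ref refractory period (ms)
#' @return expected empirical rate (Hz)
#' @export
expected_afferent_rate <- function(nu, dt = 0.1, tau_ref = 5) {
  p <- nu * dt / 1000
  (p / (dt / 1000)) * (1 - p)^(tau_ref / dt)
}

#' Draw a refractory-corrected Bernoulli spike train (reference
#' implementation)
#'
#' Per-step Bernoulli draws with probability `rate * dt`, suppressed for
#' `tau_ref` after each accepted spike.  This is the pure-R reference
#' route used by the test suite to validate the C++ generator; it is exact
#' (it draws every step) and therefore only suitable for single afferents
#' or short durations.
#'
#' @param rate rate (Hz); a scalar, or a vector with one entry per step for
#'   inhomogeneous rates
#' @param duration total time (ms)
#' @param dt time step (ms)
#' @param tau_ref refractory period (ms)
#' @return spike times (ms), at step boundaries `(step index) * dt`
#' @export
draw_spike_train <- function(rate, duration, dt = 0.1, tau_ref = 5) {
  n_steps <- round(duration / dt)
  p <- rate * dt / 1000
  if (any(p >= 1)) stop("draw_spike_train: rate * dt must be < 1")
  if (length(p) == 1L) p <- rep(p, n_steps)
  if (length(p) != n_steps)
    stop("draw_spike_train: rate must be scalar or one value per step")
  cand <- which(stats::runif(n_steps) < p)
  if (length(cand) == 0L) return(numeric(0))
  nref <- round(tau_ref / dt)
  keep <- integer(length(cand))
  m <- 0L
  last <- -nref - 1L
  for (s in cand) {
    if (s - last > nref) {
      m <- m + 1L
      keep[m] <- s
      last <- s
    }
  }
  keep[seq_len(m)] * dt
}

#' Generate a natural-input spike raster in R (reference implementation)
#'
#' Small-scale pure-R generator of the OU-modulated input: one OU
#' trajectory per signal group, shared by all afferents of the group
#' (excitatory and inhibitory alike), and independent refractory-corrected
#' Bernoulli thinning per afferent.  Used for desk-scale fixtures and as an
#' independent check of the C++ generator's statistics.
#'
#' @param arch an [input_architecture()]
#' @param duration total time (ms)
#' @param rates a [rate_params()]
#' @param dt time step (ms)
#' @param gains inhibitory gain per population
#' @return list with `time` (ms), `afferent` (index), and `y` (matrix of OU
#'   values, one column per group, one row per dT update)
#' @export
generate_natural_raster <- function(arch, duration, rates = rate_params(),
                                    dt = 0.1, gains = rep(1, arch$n_inh_pops)) {
  n_blocks <- round(duration / rates$dT)
  steps_per_block <- round(rates$dT / dt)
  y <- matrix(0, n_blocks, arch$n_groups)
  sd0 <- ou_stationary_sd(rates$tau_OU, rates$dT)
  prev <- stats::rnorm(arch$n_groups, 0, sd0)
  for (b in seq_len(n_blocks)) {
    prev <- ou_step(prev, rates$tau_OU, rates$dT)
    y[b, ] <- prev
  }
  times <- list(); ids <- list(); idx <- 1L
  for (j in seq_len(arch$n)) {
    g <- arch$group[j]
    if (arch$pop[j] == 0L) {
      r_blocks <- group_rate(y[, g], "exc", rates)
      tref <- rates$tau_Eref
    } else {
      r_blocks <- group_rate(y[, g], "inh", rates, gain = gains[arch$pop[j]])
      tref <- rates$tau_Iref
    }
    r_steps <- rep(r_blocks, each = steps_per_block)
    st <- draw_spike_train(r_steps, duration, dt, tref)
    if (length(st)) {
      times[[idx]] <- st
      ids[[idx]] <- rep(j, length(st))
      idx <- idx + 1L
    }
  }
  tm <- unlist(times); id <- unlist(ids)
  if (is.null(tm)) tm <- numeric(0)
  if (is.null(id)) id <- integer(0)
  o <- order(tm, id)
  list(time = tm[o], afferent = id[o], y = y)
}
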