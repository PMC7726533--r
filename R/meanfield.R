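#' Mean-field fixed point of the Hebbian rule
#'
#' Neglecting pre/post spike correlations, the Hebbian rule drives the
#' postsynaptic rate to the stable fixed point
#' `rho_0 = alpha_H / (2 * tau_STDP)`; with `tau_STDP` in ms the result is
#' converted to Hz.  At the defaults (`alpha_H = 0.2`, `tau_STDP = 20 ms`)
#' this is exactly 5 Hz.
#'
#' @param alpha_H depression bias
#' @param tau_STDP trace time constant (ms)
#' @return list with `rate` (Hz), `stability = "stable"`, `rule = "hebbian"`
#' @export
hebbian_fixed_point <- function(alpha_H = 0.2, tau_STDP = 20) {
  if (tau_STDP <= 0) stop("hebbian_fixed_point: tau_STDP must be > 0")
  if (alpha_H < 0) stop("hebbian_fixed_point: alpha_H must be >= 0")
  structure(list(rate = 1000 * alpha_H / (2 * tau_STDP),
                 stability = "stable", rule = "hebbian"),
            class = "meanfield_result")
}

#' Mean-field threshold of the anti-Hebbian rule
#'
#' The anti-Hebbian rule has an unstable threshold at
#' `rho_1 = alpha_aH / (2 * tau_STDP)`: the closed-loop rate drifts away
#' from it (up above, down below).
#'
#' @param alpha_aH potentiation bias
#' @param tau_STDP trace time constant (ms)
#' @return list with `rate` (Hz), `stability = "unstable"`,
#'   `rule = "anti_hebbian"`
#' @export
antihebbian_threshold <- function(alpha_aH = 0.165, tau_STDP = 20) {
  if (tau_STDP <= 0) stop("antihebbian_threshold: tau_STDP must be > 0")
  if (alpha_aH < 0) stop("antihebbian_threshold: alpha_aH must be >= 0")
  structure(list(rate = 1000 * alpha_aH / (2 * tau_STDP),
                 stability = "unstable", rule = "anti_hebbian"),
            class = "meanfield_result")
}

#' @export
print.meanfield_result <- function(x, ...) {
  cat(sprintf("Mean-field %s rule: fixed point %.4g Hz (%s)\n",
              x$rule, x$rate, x$stability))
  invisible(x)
}

#' Reduced rate iteration around a plasticity fixed point
#'
#' Sign-level mean-field dynamics: the rate change per iteration is
#' proportional to `(rho - rate)` for the stable Hebbian rule and to
#' `(rate - rho)` for the unstable anti-Hebbian rule.  Used as an analytic
#' oracle for drift-direction tests; the proportionality constant is not
#' specified by the theory, only the sign and the fixed point are.
#'
#' @param rate initial rate (Hz)
#' @param rule `"hebbian"` or `"anti_hebbian"`
#' @param rho fixed-point/threshold rate (Hz)
#' @param gain step size of the iteration
#' @param n_iter number of iterations
#' @return vector of rates, starting value first
#' @export
rate_drift <- function(rate, rule = c("hebbian", "anti_hebbian"),
                       rho = 5, gain = 0.1, n_iter = 10) {
  rule <- match.arg(rule)
  out <- numeric(n_iter + 1)
  out[1] <- rate
  for (i in seq_len(n_iter)) {
    d <- if (rule == "hebbian") rho - out[i] else out[i] - rho
    out[i + 1] <- max(0, out[i] + gain * d)
  }
  out
}

#' Closed-form weight under an alternating LTD/LTP scaling schedule
#'
#' Evaluates the exact solution of the scaling rule for a schedule of
#' alternating depression and potentiation intervals with constant rate
#' estimates: each LTD interval of length `t` multiplies the weight by
#' `exp(-eta_s * y_ltd * t)`, each LTP interval adds
#' `eta_s * w_Is * y_ltp * t`.  For long schedules the memory of the
#' initial weight decays and the limiting weight is independent of `w0`.
#'
#' Interval durations are in units of the reference step (`dt_ref`) times
#' ms, i.e. the same convention as the online rule: an interval of `t` ms
#' contributes an exponent `eta_s * y_ltd * t / dt_ref`.
#'
#' @param ltd_intervals durations of the LTD intervals (ms)
#' @param ltp_intervals durations of the LTP intervals (ms); the schedule is
#'   taken as LTP_1, LTD_1, LTP_2, LTD_2, ... and the interval counts may
#'   differ by at most one
#' @param w0 initial weight(s); vectorised
#' @param y_ltd mean depression drive `rho_0 - y_post` during LTD (Hz)
#' @param y_ltp mean potentiation drive `y_post - rho_0` during LTP (Hz)
#' @param params a [scaling_params()]
#' @return matrix with one row per `w0`: columns `w0` and `w_final`
#' @export
scaling_limit_weight <- function(ltd_intervals, ltp_intervals, w0,
                                 y_ltd = 2.5, y_ltp = 2.5,
                                 params = scaling_params()) {
  n_ltd <- length(ltd_intervals); n_ltp <- length(ltp_intervals)
  if (n_ltd == 0 && n_ltp == 0)
    stop("scaling_limit_weight: empty schedule")
  if (abs(n_ltd - n_ltp) > 1)
    stop("scaling_limit_weight: interval counts must alternate (differ by <= 1)")
  eta <- params$eta_s / params$dt_ref
  w_final <- vapply(w0, function(wi) {
    w <- wi
    for (i in seq_len(max(n_ltd, n_ltp))) {
      if (i <= n_ltp) w <- w + eta * params$w_Is * y_ltp * ltp_intervals[i]
      if (i <= n_ltd) w <- w * exp(-eta * y_ltd * ltd_intervals[i])
    }
    w
  }, numeric(1))
  cbind(w0 = w0, w_final = w_final)
}
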