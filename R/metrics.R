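#' Low-pass filter a (pooled) spike train
#'
#' Leaky integration `tau * dX/dt = -X + S(t)` sampled on the `dt` grid:
#' exponential decay by `exp(-dt/tau)` per step and a jump of `1/tau` per
#' spike (so a single spike has impulse response `exp(-(t - t0)/tau)/tau`).
#' The filter is linear: filtering a superposition of trains equals the sum
#' of the filtered trains.
#'
#' @param spike_times spike times (ms); pooled over afferents if pooling is
#'   wanted
#' @param duration total time (ms)
#' @param dt sampling step (ms)
#' @param tau filter time constant (ms)
#' @return numeric vector of the filtered signal at `dt, 2*dt, ..., duration`
#' @export
lowpass_trace <- function(spike_times, duration, dt = 0.1, tau = 10) {
  (1 / tau) * trace_online(spike_times, duration, dt = dt, tau_STDP = tau)
}

#' Pearson correlation with explicit zero-variance handling
#'
#' Standard Pearson coefficient over the whole series; if either series has
#' zero variance the correlation is undefined and `NA` is returned (with a
#' warning) rather than 0.
#'
#' @param z,y numeric series of equal length (>= 2)
#' @return correlation in `[-1, 1]`, or `NA_real_`
#' @export
pearson_cor <- function(z, y) {
  if (length(z) != length(y)) stop("pearson_cor: series must have equal length")
  if (length(z) < 2) stop("pearson_cor: need at least 2 samples")
  if (stats::sd(z) == 0 || stats::sd(y) == 0) {
    warning("pearson_cor: zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(z, y)
}

#' Receptive-field performance index
#'
#' `delta_C = (C_pref - C_nonpref) / 2`: +1 when the output correlates only
#' with the preferred group, -1 when only with the nonpreferred group, 0
#' for an indiscriminate response.  Swapping the two groups flips the sign.
#'
#' @param C per-group correlation vector
#' @param preferred index of the preferred group
#' @param nonpreferred index of the nonpreferred group
#' @return performance index in `[-1, 1]`
#' @export
performance_index <- function(C, preferred = 9L, nonpreferred = 1L) {
  if (preferred > length(C) || nonpreferred > length(C))
    stop("performance_index: group index out of range")
  (C[preferred] - C[nonpreferred]) / 2
}

#' Coefficient of variation of interspike intervals
#'
#' `CV_ISI = SD(ISI) / mean(ISI)`: 0 for a periodic train, 1 for a Poisson
#' process, below 1 under refractoriness, above 1 for bursty trains.
#'
#' @param spike_times ordered spike times (ms); at least 3 spikes
#' @return CV of the ISIs, or `NA_real_` (with a warning) for < 3 spikes
#' @export
cv_isi <- function(spike_times) {
  if (length(spike_times) < 3) {
    warning("cv_isi: need at least 3 spikes; returning NA")
    return(NA_real_)
  }
  isi <- diff(spike_times)
  stats::sd(isi) / mean(isi)
}

#' Mean rate and rate SD of a spike train
#'
#' Mean rate is total count over duration; the SD is computed over
#' non-overlapping bins (1 s by default).
#'
#' @param spike_times spike times (ms)
#' @param duration total time (ms)
#' @param bin bin width (ms) for the SD
#' @return list with `mean` (Hz), `sd` (Hz), `n_spikes`
#' @export
rate_stats <- function(spike_times, duration, bin = 1000) {
  n_bins <- max(1L, floor(duration / bin))
  inside <- spike_times <= n_bins * bin
  counts <- tabulate(pmin(floor(spike_times[inside] / bin) + 1L, n_bins),
                     nbins = n_bins)
  list(mean = length(spike_times) / (duration / 1000),
       sd = stats::sd(counts * 1000 / bin),
       n_spikes = length(spike_times))
}

#' Pulse response from trial spike counts
#'
#' `(mean count at k - mean count at k = 0) * 20`: the factor 20 converts a
#' count over a 50 ms window into Hz.  Subtracting the matched k = 0
#' (background-only) trials isolates the response to the extra step input.
#'
#' @param counts_k spike counts in the window, one per trial at amplitude k
#' @param counts_0 spike counts in the same window for k = 0 trials
#' @return baseline-subtracted response (Hz)
#' @export
pulse_response <- function(counts_k, counts_0) {
  (mean(counts_k) - mean(counts_0)) * 20
}

#' Signals recovered from per-group pulse responses
#'
#' Counts the signal groups whose response is strictly greater than half
#' the maximum group response (ties at exactly half are excluded).
#'
#' @param responses per-group (phasic) response vector (Hz)
#' @return list with `count`, `fraction`, and the logical `recovered` mask
#' @export
signals_recovered <- function(responses) {
  if (all(responses <= 0)) {
    return(list(count = 0L, fraction = 0,
                recovered = rep(FALSE, length(responses))))
  }
  rec <- responses > max(responses) / 2
  list(count = sum(rec), fraction = mean(rec), recovered = rec)
}
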