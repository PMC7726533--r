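#' Excitatory tuning profile over signal groups
#'
#' Evaluates the receptive-field profile
#' `r(mu) = 1/(1 + r0) + (r0/(1 + r0)) / (1 + b * (mu - mu0)^c)`.
#' The profile equals 1 at the preferred group `mu0`, decreases
#' monotonically and symmetrically with `|mu - mu0|` (for even `c`), and is
#' bounded below by `1/(1 + r0)`.  Group distance is plain `(mu - mu0)`;
#' there is no wrap-around across group boundaries.
#'
#' @param mu signal-group index (1-based), vectorised
#' @param params a [tuning_params()]
#' @return profile values in `(0, 1]`
#' @export
tuning_profile <- function(mu, params = tuning_params()) {
  1 / (1 + params$r0) +
    (params$r0 / (1 + params$r0)) / (1 + params$b * (mu - params$mu0)^params$c)
}

#' Initialise excitatory weights from the tuning profile
#'
#' `w_j = w_E0 * r(group_j) + eps_j` with `eps_j` uniform on
#' `[-eps_E, eps_E]`, clipped at 0.  Excitatory weights remain fixed during
#' simulations.
#'
#' @param arch an [input_architecture()]
#' @param tuning a [tuning_params()]
#' @param w_E0 baseline weight
#' @param eps_E noise half-width
#' @return numeric vector over all afferents: excitatory entries hold the
#'   tuned weights, inhibitory entries are 0
#' @export
init_excitatory_weights <- function(arch, tuning = tuning_params(),
                                    w_E0 = 0.5, eps_E = 0.01) {
  w <- numeric(arch$n)
  exc <- arch$pop == 0L
  n_e <- sum(exc)
  w[exc] <- w_E0 * tuning_profile(arch$group[exc], tuning) +
    stats::runif(n_e, -eps_E, eps_E)
  pmax(w, 0)
}

#' Initialise flat inhibitory weights
#'
#' All inhibitory afferents of population `pop` receive `w_IF` plus
#' independent uniform noise on `[-eps_I, eps_I]`, clipped at 0.
#'
#' @param arch an [input_architecture()]
#' @param pop inhibitory population index (1 or 2)
#' @param w_IF baseline weight
#' @param eps_I noise half-width
#' @return numeric vector over all afferents; entries outside the chosen
#'   population are 0
#' @export
init_inhibitory_weights <- function(arch, pop = 1L, w_IF = 0.4, eps_I = 0.01) {
  w <- numeric(arch$n)
  sel <- arch$pop == pop
  w[sel] <- w_IF + stats::runif(sum(sel), -eps_I, eps_I)
  pmax(w, 0)
}

#' Weight table for export
#'
#' @param arch an [input_architecture()]
#' @param w weight vector over all afferents
#' @return data.frame with columns afferent, population, group, weight
#' @export
weight_table <- function(arch, w) {
  stopifnot(length(w) == arch$n)
  data.frame(afferent = seq_len(arch$n), population = arch$pop,
             group = arch$group, weight = w)
}

#' Per-group mean weights of one population
#'
#' @param arch an [input_architecture()]
#' @param w weight vector
#' @param pop population selector (0 excitatory, 1/2 inhibitory)
#' @return named numeric vector of length `n_groups`
#' @export
group_mean_weights <- function(arch, w, pop) {
  sel <- arch$pop == pop
  out <- tapply(w[sel], arch$group[sel], mean)
  as.numeric(out[as.character(seq_len(arch$n_groups))])
}
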