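#' Afferent population layout
#'
#' Builds the signal-group architecture: `n_groups` signal groups, each
#' holding `n_exc_per_group` excitatory afferents and, per inhibitory
#' population, `n_inh_per_group[i]` inhibitory afferents.  Afferents are
#' numbered 1..N with all excitatory afferents first (grouped by signal
#' group), followed by inhibitory population 1, then population 2.
#'
#' Defaults reproduce the full-scale two-population layout: 16 groups x
#' (200 excitatory + 2 x 25 inhibitory) = 3200 excitatory and 800
#' inhibitory afferents.
#'
#' @param n_groups number of signal groups P
#' @param n_exc_per_group excitatory afferents per group
#' @param n_inh_per_group inhibitory afferents per group for each
#'   population; a vector of length `n_inh_pops`
#' @param n_inh_pops number of inhibitory populations (1 or 2)
#' @return object of class `input_architecture` with fields `n`, `n_exc`,
#'   `n_inh`, `n_groups`, `group` (group index per afferent, 1-based) and
#'   `pop` (0 = excitatory, `i` = inhibitory population i)
#' @export
input_architecture <- function(n_groups = 16, n_exc_per_group = 200,
                               n_inh_per_group = c(25, 25),
                               n_inh_pops = length(n_inh_per_group)) {
  n_groups <- as.integer(n_groups)
  n_exc_per_group <- as.integer(n_exc_per_group)
  n_inh_pops <- as.integer(n_inh_pops)
  if (length(n_inh_per_group) == 1L)
    n_inh_per_group <- rep(n_inh_per_group, n_inh_pops)
  n_inh_per_group <- as.integer(n_inh_per_group)
  if (n_groups < 1 || n_exc_per_group < 1 || any(n_inh_per_group < 1))
    stop("input_architecture: counts must be >= 1")
  if (length(n_inh_per_group) != n_inh_pops)
    stop("input_architecture: n_inh_per_group must have one entry per inhibitory population")

  group <- rep(seq_len(n_groups), each = n_exc_per_group)
  pop <- rep(0L, n_groups * n_exc_per_group)
  for (i in seq_len(n_inh_pops)) {
    group <- c(group, rep(seq_len(n_groups), each = n_inh_per_group[i]))
    pop <- c(pop, rep(i, n_groups * n_inh_per_group[i]))
  }
  structure(list(
    n = length(group),
    n_exc = n_groups * n_exc_per_group,
    n_inh = sum(n_inh_per_group) * n_groups,
    n_groups = n_groups,
    n_exc_per_group = n_exc_per_group,
    n_inh_per_group = n_inh_per_group,
    n_inh_pops = n_inh_pops,
    group = as.integer(group),
    pop = as.integer(pop)
  ), class = "input_architecture")
}

#' @export
print.input_architecture <- function(x, ...) {
  cat("Input architecture:", x$n_groups, "signal groups\n")
  cat("  excitatory:", x$n_exc, sprintf("(%d per group)\n", x$n_exc_per_group))
  cat("  inhibitory:", x$n_inh,
      sprintf("(%s per group, %d population%s)\n",
              paste(x$n_inh_per_group, collapse = " + "),
              x$n_inh_pops, if (x$n_inh_pops > 1) "s" else ""))
  invisible(x)
}

#' Indices of the afferents of one population
#'
#' @param arch an [input_architecture()]
#' @param pop 0 for excitatory, or the inhibitory population number
#' @return integer vector of afferent indices
#' @export
population_indices <- function(arch, pop) {
  which(arch$pop == pop)
}
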