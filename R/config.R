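#' Default run configuration
#'
#' The full parameter set of the standard model as a nested list, one
#' section per component: `neuron`, `architecture`, `rates`, `pulse`,
#' `tuning`, `weights`, `plasticity` (with sub-sections `hebbian`,
#' `scaling`, `antihebbian`), `metrics`, and `experiment`.  Times are in
#' ms, rates in Hz, voltages in mV, weights dimensionless.  Every field can
#' be overridden via a YAML configuration file ([load_config()]).
#'
#' `weights$w_IF` and `weights$eps_I` default to `NULL`, meaning "choose by
#' rule combination" (see [isp_model()]): 0.4/0.01 for a single inhibitory
#' population, 0.8/0.3 for Hebbian + scaling, 0.55/0.01 for Hebbian +
#' anti-Hebbian, 0.8/0.01 otherwise.
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    neuron = list(tau_m = 30, u_rest = -65, E_E = 0, E_I = -80, tau_E = 5,
                  tau_I = 10, u_th = -50, u_reset = -65, tau_ref = 5, dt = 0.1),
    architecture = list(n_groups = 16, n_exc_per_group = 200,
                        n_inh_per_group = 25, n_inh_per_group_single = 50),
    rates = list(nu_E0 = 5, nu_I0 = 10, nu_Ebg = 2, nu_Ibg = 4,
                 tau_Eref = 5, tau_Iref = 2.5, tau_OU = 50, dT = 1),
    pulse = list(nu_star = 5, alpha_E = 1, alpha_I = 2, duration = 100),
    tuning = list(r0 = 4, b = 0.25, c = 2, mu0 = 9),
    weights = list(w_E0 = 0.5, eps_E = 0.01, w_IF = NULL, eps_I = NULL),
    plasticity = list(
      tau_STDP = 20,
      hebbian = list(eta_H = 1e-3, alpha_H = 0.2),
      scaling = list(eta_s = 1e-7, w_Is = 0.8, rho_0 = 5, alpha_s = 2,
                     tau_scaling = 1000, dt_ref = 0.1),
      antihebbian = list(eta_aH_star = 1e-3, tau_aH = 250e3, alpha_aH = 0.165,
                         t0 = 0)
    ),
    metrics = list(tau_Z = 10, tau_Y = 250, burn_in = 5000, rate_bin = 1000),
    experiment = list(train_min = 30, probe_min = 5, pulse_trials = 100,
                      pulse_settle = 200, compensate_tol = 0.1,
                      compensate_bracket = c(0.5, 5))
  )
}

merge_config <- function(base, override, path = "") {
  for (nm in names(override)) {
    here <- if (path == "") nm else paste0(path, "$", nm)
    if (!nm %in% names(base))
      stop("unknown configuration key: '", here, "'")
    if (is.list(base[[nm]]) && length(base[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      if (!is.list(override[[nm]]))
        stop("configuration key '", here, "' must be a section")
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    } else {
      base[nm] <- override[nm]
    }
  }
  base
}

#' Validate a configuration list
#'
#' Runs every section through its parameter constructor so that all
#' invariants (reversal-potential ordering, positive time constants,
#' `dt <= min(tau_E, tau_I)/10`, dead-zone factor > 1, ...) are enforced;
#' errors name the offending key.
#'
#' @param config nested configuration list
#' @return the config, invisibly, if valid
#' @export
validate_config <- function(config) {
  do.call(neuron_params, config$neuron)
  do.call(rate_params, config$rates)
  do.call(tuning_params, config$tuning)
  do.call(hebbian_params, c(config$plasticity$hebbian,
                            list(tau_STDP = config$plasticity$tau_STDP)))
  do.call(scaling_params, config$plasticity$scaling)
  do.call(antihebbian_params, c(config$plasticity$antihebbian,
                                list(tau_STDP = config$plasticity$tau_STDP)))
  filter_params(config$metrics$tau_Z, config$metrics$tau_Y)
  with(config$architecture, {
    if (n_groups < 1 || n_exc_per_group < 1 || n_inh_per_group < 1)
      stop("configuration: architecture counts must be >= 1")
  })
  if (config$pulse$nu_star < 0 || config$pulse$duration <= 0)
    stop("configuration: pulse$nu_star >= 0 and pulse$duration > 0 required")
  invisible(config)
}

#' Load a configuration file
#'
#' Reads a YAML file and merges it onto [default_config()].  An empty file
#' yields the full defaults; unknown keys are rejected by name; the merged
#' configuration is validated.
#'
#' @param path YAML file path
#' @return validated configuration list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  cfg
}

#' Write a configuration file
#'
#' @param config configuration list
#' @param path output YAML path
#' @return `path`, invisibly
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Hash of a configuration
#'
#' Stable content hash of the YAML rendering, used in run manifests.
#'
#' @param config configuration list
#' @return 8-hex-digit character hash
#' @export
config_hash <- function(config) {
  text_hash(yaml::as.yaml(config))
}

#' Write a run manifest
#'
#' Records everything needed to re-run a session bit-identically: the
#' configuration (inline and as a hash), every RNG seed used, and the
#' package version.
#'
#' @param dir run directory (created if missing)
#' @param config configuration list
#' @param seeds named list or vector of RNG seeds
#' @param extra optional named list of additional entries
#' @return manifest path, invisibly
#' @export
write_manifest <- function(dir, config, seeds, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config_yaml <- yaml::as.yaml(config)
  manifest <- c(list(
    package = "ispneuron",
    version = as.character(utils::packageVersion("ispneuron")),
    config_hash = text_hash(config_yaml),
    seeds = as.list(seeds),
    config_yaml = config_yaml
  ), extra)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path manifest file or run directory
#' @return manifest list; errors if the file is missing or its stored
#'   config hash does not match the stored config
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.yaml")
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- yaml::read_yaml(path)
  if (is.null(m$config_yaml) || is.null(m$config_hash))
    stop("corrupted manifest: missing config or config_hash")
  if (!identical(text_hash(m$config_yaml), m$config_hash))
    stop("corrupted manifest: config hash mismatch")
  m$config <- yaml::yaml.load(m$config_yaml)
  m
}
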