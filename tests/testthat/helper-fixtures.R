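# Heavy simulations shared across test files, computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# Single Hebbian inhibitory population at quarter scale (800 exc / 200 inh,
# 8 groups), 5 min of natural input.  Seeds fixed: model 1, training 2.
fixture_hebbian_training <- function() fixture("hebbian_training", {
  m <- isp_model("hebbian", scale = 0.25, seed = 1)
  train_inhibition(m, duration = 300e3, seed = 2)
})

# Two-population Hebbian + scaling model at quarter scale, trained for the
# scaled default duration (7.5 min).
fixture_hs_training <- function() fixture("hs_training", {
  m <- isp_model(c("hebbian", "scaling"), scale = 0.25, seed = 1)
  train_inhibition(m, seed = 2)
})

# Same protocol, differing only in the initial weight draw.
fixture_hs_training_alt <- function() fixture("hs_training_alt", {
  m <- isp_model(c("hebbian", "scaling"), scale = 0.25, seed = 99)
  train_inhibition(m, seed = 2)
})

# A small architecture for desk-scale raster tests.
tiny_arch <- function(n_inh_pops = 1) {
  input_architecture(n_groups = 2, n_exc_per_group = 5,
                     n_inh_per_group = rep(2, n_inh_pops),
                     n_inh_pops = n_inh_pops)
}

tiny_model <- function(rules = "hebbian", seed = 1, config = default_config()) {
  cfg <- config
  cfg$architecture$n_groups <- 2
  cfg$architecture$n_exc_per_group <- 5
  cfg$architecture$n_inh_per_group <- 2
  cfg$architecture$n_inh_per_group_single <- 2
  cfg$tuning$mu0 <- 1
  isp_model(rules, scale = 1, config = cfg, seed = seed)
}
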