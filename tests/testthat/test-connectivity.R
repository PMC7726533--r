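test_that("tuning profile evaluates, peaks at the preferred group, and is symmetric", {
  tp <- tuning_params()
  expect_identical(tuning_profile(9, tp), 1)
  expect_equal(tuning_profile(1, tp), 0.2 + 0.8 / (1 + 0.25 * 64),
               tolerance = 1e-12)
  expect_equal(tuning_profile(1, tp), 0.24706, tolerance = 1e-4)
  expect_equal(tuning_profile(10, tp), 0.84)
  # symmetry about mu0 for even c
  d <- 1:7
  expect_equal(tuning_profile(9 + d, tp), tuning_profile(9 - d, tp))
  # monotone decrease with |mu - mu0| and range (1/(1+r0), 1]
  r <- tuning_profile(9:16, tp)
  expect_true(all(diff(r) < 0))
  expect_true(all(r > 1 / (1 + tp$r0) & r <= 1))
})

test_that("tuning parameter constraints are enforced", {
  expect_error(tuning_params(r0 = 0.5), "r0")
  expect_error(tuning_params(b = 0), "b")
  expect_error(tuning_params(c = 3), "even")
})

test_that("excitatory initialisation reproduces the profile with bounded noise", {
  arch <- input_architecture(16, 50, 25, 1)
  set.seed(1)
  w <- init_excitatory_weights(arch, eps_E = 0)
  exc <- arch$pop == 0
  expect_equal(w[exc], 0.5 * tuning_profile(arch$group[exc]))
  expect_true(all(w[!exc] == 0))
  # preferred-group weights are exactly w_E0 when noise is off
  expect_true(all(w[exc & arch$group == 9] == 0.5))

  set.seed(2)
  w2 <- init_excitatory_weights(arch, eps_E = 0.01)
  gm <- group_mean_weights(arch, w2, 0)
  expect_true(all(abs(gm - 0.5 * tuning_profile(1:16)) < 0.01))
  set.seed(2)
  w3 <- init_excitatory_weights(arch, eps_E = 0.01)
  expect_identical(w2, w3)
})

test_that("inhibitory initialisation is flat with noise and clipped at zero", {
  arch <- input_architecture(4, 5, 10, 2)
  set.seed(3)
  w <- init_inhibitory_weights(arch, pop = 2, w_IF = 0.8, eps_I = 0)
  expect_true(all(w[arch$pop == 2] == 0.8))
  expect_true(all(w[arch$pop != 2] == 0))
  set.seed(4)
  w2 <- init_inhibitory_weights(arch, pop = 1, w_IF = 0.05, eps_I = 0.3)
  expect_true(all(w2[arch$pop == 1] >= 0))
  expect_true(any(w2[arch$pop == 1] == 0))  # clipping engaged
})

test_that("rule combinations pick their standard initial inhibitory weights", {
  m1 <- isp_model("hebbian", scale = 0.25, seed = 1)
  expect_equal(m1$w_IF, 0.4)
  expect_equal(m1$eps_I, 0.01)
  m2 <- isp_model(c("hebbian", "scaling"), scale = 0.25, seed = 1)
  expect_equal(m2$w_IF, c(0.8, 0.8))
  expect_equal(m2$eps_I, c(0.3, 0.3))
  m3 <- isp_model(c("hebbian", "anti_hebbian"), scale = 0.25, seed = 1)
  expect_equal(m3$w_IF, c(0.55, 0.55))
  expect_equal(m3$eps_I, c(0.01, 0.01))
})

test_that("scaled models preserve counts, drive, and tuning contrast", {
  m <- isp_model("hebbian", scale = 0.25, seed = 1)
  expect_identical(m$arch$n_exc, 800L)
  expect_identical(m$arch$n_inh, 200L)
  expect_identical(m$arch$n_groups, 8L)
  expect_identical(m$preferred, 5L)
  # excitatory baseline doubled: per-group drive preserved
  expect_equal(m$w_E0_eff * m$arch$n_exc_per_group, 0.5 * 200)
  # endpoint tuning contrast matches the full-scale profile
  expect_equal(tuning_profile(1, m$tuning),
               tuning_profile(1, tuning_params()), tolerance = 1e-9)
  # weight table export round-trips
  f <- tempfile(fileext = ".tsv")
  write_weights(m$arch, m$weights, f)
  back <- read_weights(f)
  expect_equal(back$weight, m$weights)
  expect_identical(back$group, m$arch$group)
  unlink(f)
})
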