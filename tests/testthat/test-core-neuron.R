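test_that("resting state is a fixed point and relaxation follows the Euler step", {
  p <- neuron_params()
  st <- lif_state(p)
  res <- lif_step(st, p)
  expect_equal(res$state$u, p$u_rest)
  expect_false(res$spiked)

  st$u <- -55
  res <- lif_step(st, p)
  # du = (dt/tau_m) * (u_rest - u) = (0.1/30) * (-10) = -1/30
  expect_equal(res$state$u, -55 - 1 / 30, tolerance = 1e-12)
})

test_that("a presynaptic spike increments the conductance by exactly its weight", {
  p <- neuron_params()
  st <- lif_state(p)
  res <- lif_step(st, p, dg_E = 0.5)
  expect_identical(res$state$g_E, 0.5)
  res2 <- lif_step(res$state, p, dg_I = 1.25)
  expect_equal(res2$state$g_I, 1.25)
  # and the previous excitatory conductance decayed by one Euler factor
  expect_equal(res2$state$g_E, 0.5 * (1 - p$dt / p$tau_E))
})

test_that("conductance decay matches the closed form within the Euler error bound", {
  p <- neuron_params()
  st <- lif_state(p)
  st$g_E <- 2; st$g_I <- 1.5
  k <- 200
  for (i in seq_len(k)) st <- lif_step(st, p)$state
  expect_equal(st$g_E, 2 * (1 - p$dt / p$tau_E)^k, tolerance = 1e-12)
  expect_equal(st$g_I, 1.5 * (1 - p$dt / p$tau_I)^k, tolerance = 1e-12)
  # Euler vs exact exponential: relative error below k * (dt/tau)^2 / 2
  expect_lt(abs(st$g_E - 2 * exp(-k * p$dt / p$tau_E)) / st$g_E,
            k * (p$dt / p$tau_E)^2)
})

test_that("parameter invariants are enforced", {
  expect_error(neuron_params(E_I = -60), "E_I < u_rest")
  expect_error(neuron_params(dt = 2), "dt must be <=")
  expect_error(neuron_params(tau_m = -1), "> 0")
})

test_that("strong constant drive cannot violate the refractory period", {
  arch <- tiny_arch()
  w <- ifelse(arch$pop == 0, 5, 0)
  # every excitatory afferent fires every ms for 2 s
  times <- rep(seq(1, 2000), each = arch$n_exc)
  ids <- rep(which(arch$pop == 0), 2000)
  p <- neuron_params()
  out <- run_lif_r(p, w, arch$pop, list(time = times, afferent = ids), 2000)
  expect_gt(length(out$spikes), 100)
  expect_true(all(diff(out$spikes) > p$tau_ref))
  expect_lte(length(out$spikes) / 2, 200)  # Hz
})

test_that("kernel and pure-R reference integrate a raster identically", {
  model <- tiny_model("hebbian", seed = 11)
  set.seed(21)
  raster <- generate_natural_raster(model$arch, 2000, model$rates)
  ref <- run_lif_r(model$neuron, model$weights, model$arch$pop, raster, 2000,
                   record_trace = TRUE)
  ses <- simulate_session(model, 2000, input = "raster", raster = raster,
                          correlation = FALSE, trace_stride = 1)
  expect_equal(ses$spikes, ref$spikes)
  expect_equal(ses$trace$u, ref$trace$u, tolerance = 1e-12)
  expect_equal(ses$trace$g_E, ref$trace$g_E, tolerance = 1e-12)
  expect_equal(ses$trace$g_I, ref$trace$g_I, tolerance = 1e-12)
})

test_that("zero-weight afferents produce no output spikes", {
  model <- tiny_model("hebbian", seed = 2)
  model$weights[] <- 0
  s <- simulate_session(model, 5000, seed = 3, correlation = FALSE)
  expect_length(s$spikes, 0)
})

test_that("identical seeds give bit-identical sessions", {
  model <- tiny_model("hebbian", seed = 4)
  a <- simulate_session(model, 5000, seed = 7, plasticity = TRUE,
                        correlation = FALSE)
  b <- simulate_session(model, 5000, seed = 7, plasticity = TRUE,
                        correlation = FALSE)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$weights, b$weights)
  c <- simulate_session(model, 5000, seed = 8, correlation = FALSE)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("voltage stays within the reversal-potential bounds", {
  model <- tiny_model("hebbian", seed = 5)
  s <- simulate_session(model, 10e3, seed = 6, trace_stride = 1,
                        correlation = FALSE)
  p <- model$neuron
  expect_true(all(s$trace$u >= p$E_I & s$trace$u <= p$E_E))
})

test_that("non-finite state aborts naming the offending quantity", {
  p <- neuron_params()
  st <- lif_state(p)
  expect_error(lif_step(st, p, dg_E = Inf), "non-finite")
  expect_error(lif_step(st, p, dg_E = Inf), "g_E|membrane")
})

test_that("spike records round-trip through both text and binary formats", {
  tm <- c(0.1, 5.3, 900.4)
  id <- c(3L, -1L, 12L)
  f1 <- tempfile(fileext = ".tsv")
  write_spikes(tm, id, f1)
  back <- read_spikes(f1)
  expect_identical(back$time, tm)
  expect_identical(back$afferent, id)
  f2 <- tempfile(fileext = ".rds")
  write_spikes(tm, id, f2, format = "rds")
  back2 <- read_spikes(f2)
  expect_identical(back2$time, tm)
  expect_identical(back2$afferent, id)
  unlink(c(f1, f2))
})
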