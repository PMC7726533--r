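test_that("trace decay is exactly exponential and spikes add unit jumps", {
  # a unit trace decays to 1/e after one time constant
  x <- trace_online(0.1, duration = 20.1, dt = 0.1, tau_STDP = 20)
  expect_equal(x[length(x)], exp(-1), tolerance = 1e-12)
  expect_identical(decay_traces(0, 5), 0)
  # two spikes in the same step each contribute +1
  x2 <- trace_online(c(0.1, 0.1), duration = 0.1)
  expect_equal(x2[1], 2)
})

test_that("online traces match the brute-force sum of exponentials", {
  set.seed(7)
  for (rep in 1:5) {
    spikes <- sort(sample.int(5000, 100)) * 0.1
    dur <- 600
    online <- trace_online(spikes, dur, dt = 0.1, tau_STDP = 20)
    t_eval <- c(123.4, 300, 599.9, 600)
    oracle <- trace_closed_form(t_eval, spikes, 20)
    got <- online[round(t_eval / 0.1)]
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("Hebbian event updates have the documented arithmetic and balance point", {
  hp <- hebbian_params()
  expect_equal(hebbian_on_pre(0.5, 0, hp) - 0.5, -2e-4)      # pure depression
  expect_equal(hebbian_on_pre(0.5, 0.2, hp), 0.5)            # balance point
  expect_equal(hebbian_on_pre(0.5, 1, hp) - 0.5, 8e-4)
  expect_equal(hebbian_on_pre(1e-5, 0, hp), 0)               # floored at 0
  expect_equal(hebbian_on_post(0.5, 0, hp), 0.5)
  expect_equal(hebbian_on_post(0.5, 1, hp) - 0.5, 1e-3)
  # potentiation kernel is symmetric across spike orders: equal traces give
  # equal increments on-pre (Hebbian term) and on-post
  x <- 0.37
  expect_equal(hebbian_on_pre(0.5, x + hp$alpha_H, hp) - 0.5,
               hebbian_on_post(0.5, x, hp) - 0.5)
})

test_that("anti-Hebbian rule mirrors the Hebbian one with a decaying rate", {
  ap <- antihebbian_params()
  expect_equal(antihebbian_rate(250e3, ap), 1e-3 * exp(-1))
  expect_equal(antihebbian_rate(0, ap), 1e-3)
  expect_lt(antihebbian_rate(2e6, ap), 4e-7)  # learning rate decays to ~0
  expect_equal(antihebbian_on_pre(0.5, ap$alpha_aH, 0, ap), 0.5)  # balance
  expect_lt(antihebbian_on_pre(0.5, 1, 0, ap), 0.5)  # coincidence depresses
  expect_gt(antihebbian_on_pre(0.5, 0, 0, ap), 0.5)  # lone pre potentiates
  expect_equal(antihebbian_on_post(1e-6, 1, 0, ap), 0)  # floored at 0
})

test_that("scaling rule: dead zone, multiplicative LTD, additive LTP", {
  sp <- scaling_params()
  w <- c(0.4, 0.8)
  # inside the dead zone [2.5, 10] Hz nothing changes
  for (y in c(2.6, 5, 9.9)) {
    out <- scaling_step(w, y, FALSE, dt = 0.1, sp)
    expect_identical(out$w, w)
  }
  # silent neuron: depression proportional to the weight (ratio preserved)
  out <- scaling_step(w, 0, FALSE, dt = 0.1, sp)
  dw <- w - out$w
  expect_true(all(dw > 0))
  expect_equal(dw[2] / dw[1], 2, tolerance = 1e-9)
  # fast neuron: all weights gain the same additive amount
  out2 <- scaling_step(w, 20, FALSE, dt = 0.1, sp)
  dw2 <- out2$w - w
  expect_gt(dw2[1], 0)
  expect_equal(dw2[1], dw2[2])
  expect_equal(dw2[1], sp$eta_s * sp$w_Is * (20 * exp(-0.1 / sp$tau_scaling) - sp$rho_0))
})

test_that("the rate estimator converges to the true rate in Hz", {
  sp <- scaling_params()
  # 5 Hz periodic spiking, stepped at 1 ms for 30 s
  y <- 0
  for (s in seq_len(30e3)) {
    y <- scaling_step(numeric(0), y, post_spiked = (s %% 200 == 0),
                      dt = 1, sp)$y_post
  }
  expect_equal(y, 5, tolerance = 0.15)
})

test_that("kernel plasticity matches an independent pure-R re-implementation", {
  for (rules in list(c("hebbian", "scaling"), c("anti_hebbian", "fixed"))) {
    model <- tiny_model(rules, seed = 13)
    set.seed(29)
    raster <- generate_natural_raster(model$arch, 3000, model$rates)
    ref <- run_ref_plastic(model, raster, 3000)
    ses <- simulate_session(model, 3000, input = "raster", raster = raster,
                            plasticity = TRUE, correlation = FALSE)
    expect_equal(ses$spikes, ref$spikes)
    expect_equal(ses$weights, ref$w, tolerance = 1e-12)
    expect_equal(ses$y_post, ref$y_post, tolerance = 1e-12)
    expect_true(all(ses$weights >= 0))
  }
})

test_that("weight floors are respected by all rules in closed loop", {
  model <- tiny_model(c("hebbian", "anti_hebbian"), seed = 17)
  s <- simulate_session(model, 20e3, plasticity = TRUE, seed = 19,
                        correlation = FALSE)
  expect_true(all(s$weights >= 0))
})
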