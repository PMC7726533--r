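test_that("the OU drift has a fixed point at zero and zero stationary mean", {
  expect_identical(ou_step(0, xi = 0), 0)
  expect_equal(ou_step(10, tau_OU = 50, dT = 1, xi = 0), 10 * (1 - 1 / 50))

  set.seed(101)
  y <- ou_series(2e5)
  # effective sample size ~ n * dT / (2 * tau_OU)
  se <- ou_stationary_sd() / sqrt(2e5 / 100)
  expect_lt(abs(mean(y)), 3 * se)
  # rectification symmetry: about half the time in the active state
  expect_lt(abs(mean(y > 0) - 0.5), 0.05)
  # stationary SD close to sqrt(tau_OU / (2 dT)) = 5
  expect_equal(sd(y), ou_stationary_sd(), tolerance = 0.05)
  expect_equal(ou_stationary_sd(), 5, tolerance = 0.01)
})

test_that("group rates follow the rectified-OU formula with gain modulation", {
  expect_equal(group_rate(-3, "exc"), 2)   # background only
  expect_equal(group_rate(1, "exc"), 7)    # 5 * 1 + 2
  expect_equal(group_rate(1, "inh"), 14)   # 10 * 1 + 4
  expect_equal(group_rate(1, "inh", gain = 0), 0)
  # gain scales the full rate linearly (amplitude and background)
  y <- c(-2, 0, 0.5, 3)
  expect_equal(group_rate(y, "inh", gain = 0.7),
               0.7 * group_rate(y, "inh"))
})

test_that("pulse rates step only the target group inside the window", {
  ps <- pulse_params(k = 8, target_group = 3)
  # k = 0: background everywhere at all times
  ps0 <- pulse_params(k = 0, target_group = 3)
  expect_equal(pulse_rate(c(10, 50, 150), 3, "exc", ps0), rep(2, 3))
  # excitatory: 1 * 8 * 5 + 2 = 42 in-window
  expect_equal(pulse_rate(50, 3, "exc", ps), 42)
  # inhibitory: 2 * 8 * 5 + 4 = 84 in-window
  expect_equal(pulse_rate(50, 3, "inh", ps), 84)
  # outside the window and for non-target groups: background
  expect_equal(pulse_rate(150, 3, "exc", ps), 2)
  expect_equal(pulse_rate(50, 2, "exc", ps), 2)
})

test_that("refractory-corrected Bernoulli spiking matches its analytic rate", {
  expect_length(draw_spike_train(0, 1000), 0)
  expect_error(draw_spike_train(20000, 1000, dt = 0.1), "must be < 1")
  set.seed(11)
  a <- draw_spike_train(20, 10e3)
  set.seed(11)
  b <- draw_spike_train(20, 10e3)
  expect_identical(a, b)
  expect_true(all(diff(a) > 5 - 1e-9))

  dur <- 600e3  # 10 min
  for (nu in c(2, 20)) {
    set.seed(nu)
    st <- draw_spike_train(nu, dur, dt = 0.1, tau_ref = 5)
    expected <- expected_afferent_rate(nu, 0.1, 5)
    se <- sqrt(length(st)) / (dur / 1000)
    expect_lt(abs(length(st) / (dur / 1000) - expected), 3 * se)
  }
})

test_that("kernel-generated afferents obey the analytic rate too", {
  # single-group architecture, zero weights: the kernel only generates input
  arch <- input_architecture(2, 50, 2, 1)
  cfg <- default_config()
  cfg$architecture[c("n_groups", "n_exc_per_group")] <- list(2, 50)
  cfg$architecture[c("n_inh_per_group", "n_inh_per_group_single")] <- list(2, 2)
  cfg$rates$nu_E0 <- 0; cfg$rates$nu_Ebg <- 4  # constant 4 Hz, no modulation
  cfg$rates$nu_I0 <- 0; cfg$rates$nu_Ibg <- 4
  m <- isp_model("fixed", scale = 1, config = cfg)
  m$weights[] <- 0
  s <- simulate_session(m, 120e3, seed = 31, correlation = FALSE,
                        record_input_spikes = TRUE)
  counts <- tabulate(s$input_spikes$afferent, nbins = m$arch$n)
  emp <- mean(counts[m$arch$pop == 0]) / 120
  expected <- expected_afferent_rate(4, 0.1, 5)
  se <- sqrt(sum(counts[m$arch$pop == 0])) / 120 / sum(m$arch$pop == 0)
  expect_lt(abs(emp - expected), 3 * se)
  # inhibitory refractory period is shorter (2.5 ms)
  emp_i <- mean(counts[m$arch$pop == 1]) / 120
  expect_lt(abs(emp_i - expected_afferent_rate(4, 0.1, 2.5)),
            4 * sqrt(sum(counts[m$arch$pop == 1])) / 120 / sum(m$arch$pop == 1))
})

test_that("natural input has long-tailed ISIs and independent groups", {
  arch <- input_architecture(4, 2, 1, 1)
  set.seed(41)
  ras <- generate_natural_raster(arch, 120e3)
  # afferent-level CV of ISIs above 1 (rate modulation adds variance)
  cv <- sapply(1:4, function(j) {
    st <- ras$time[ras$afferent == j]
    sd(diff(st)) / mean(diff(st))
  })
  expect_true(all(cv > 1))
  # rates of different groups are uncorrelated ...
  expect_lt(abs(cor(ras$y[, 1], ras$y[, 2])), 3 / sqrt(120e3 / 100))
  # ... while afferents of one group share the same rate trajectory by
  # construction (the same y column drives every member)
  expect_identical(ncol(ras$y), 4L)
})

test_that("rates above the Bernoulli bound are rejected as configuration errors", {
  m <- tiny_model("hebbian", seed = 1)
  m$rates$nu_Ebg <- 2e4
  expect_error(simulate_session(m, 100, seed = 1, correlation = FALSE),
               "rate \\* dt")
})
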