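test_that("the low-pass filter has the right impulse response and is linear", {
  z <- lowpass_trace(10, duration = 50, dt = 0.1, tau = 10)
  expect_identical(sum(z[1:99]), 0)                 # nothing before the spike
  expect_equal(z[100], 1 / 10)                      # jump of 1/tau
  expect_equal(z[300], exp(-20 / 10) / 10, tolerance = 1e-12)
  # linearity: filter of a pooled train = sum of filtered trains
  a <- c(5, 17.3); b <- c(2.2, 17.3, 40)
  lhs <- lowpass_trace(c(a, b), 60)
  rhs <- lowpass_trace(a, 60) + lowpass_trace(b, 60)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("pearson correlation handles identities, affine maps and degeneracy", {
  set.seed(8)
  z <- rnorm(500)
  expect_equal(pearson_cor(z, z), 1)
  expect_equal(pearson_cor(z, -z + 3), -1)
  expect_equal(pearson_cor(z, 2.5 * z + 1), 1)
  y <- rnorm(5000); x <- rnorm(5000)
  expect_lt(abs(pearson_cor(x, y)), 3 / sqrt(5000))
  expect_warning(out <- pearson_cor(rep(1, 10), rnorm(10)), "zero variance")
  expect_true(is.na(out))
  expect_error(pearson_cor(1:3, 1:4), "equal length")
})

test_that("the performance index contrasts preferred and nonpreferred groups", {
  C <- rep(0, 16); C[9] <- 1; C[1] <- -1
  expect_identical(performance_index(C, 9, 1), 1)
  expect_identical(performance_index(rep(0.4, 16), 9, 1), 0)
  C2 <- rep(0, 16); C2[9] <- -1; C2[1] <- 1
  expect_identical(performance_index(C2, 9, 1), -1)
  # swapping the two groups flips the sign
  set.seed(9); C3 <- runif(16, -1, 1)
  expect_equal(performance_index(C3, 9, 1), -performance_index(C3, 1, 9))
  expect_error(performance_index(C3, 20, 1), "out of range")
})

test_that("CV of ISIs separates periodic, Poisson, and refractory spiking", {
  expect_equal(cv_isi(seq(0, 1000, by = 10)), 0)
  set.seed(10)
  poisson_train <- cumsum(rexp(20000, rate = 20 / 1000))
  expect_equal(cv_isi(poisson_train), 1, tolerance = 0.03)
  refr <- draw_spike_train(50, 600e3, dt = 0.1, tau_ref = 5)
  expect_lt(cv_isi(refr), 0.95)
  expect_warning(out <- cv_isi(c(1, 2)), "at least 3")
  expect_true(is.na(out))
})

test_that("rate statistics use total counts and 1 s bins", {
  st <- seq(100, 60e3, by = 200)  # 5 Hz exactly
  rs <- rate_stats(st, 60e3)
  expect_equal(rs$mean, 5)
  expect_equal(rs$sd, 0)
  expect_identical(rs$n_spikes, 300L)
})

test_that("pulse responses are baseline-subtracted and scaled to Hz", {
  expect_identical(pulse_response(rep(2, 100), rep(2, 100)), 0)
  # one extra spike per trial in a 50 ms window is +20 Hz
  expect_equal(pulse_response(rep(3, 100), rep(2, 100)), 20)
})

test_that("signals recovered counts strictly-above-half-max responses", {
  expect_identical(signals_recovered(c(10, 4, 1))$count, 1L)
  expect_identical(signals_recovered(rep(7, 16))$count, 16L)
  expect_identical(signals_recovered(c(0, 0, 0))$count, 0L)
  # a response at exactly half the maximum does not count
  expect_identical(signals_recovered(c(10, 5, 6))$count, 2L)
})

test_that("kernel online correlations agree with offline filtering", {
  model <- tiny_model("hebbian", seed = 23)
  ses <- simulate_session(model, 20e3, seed = 24, correlation = TRUE,
                          record_input_spikes = TRUE, burn_in = 5000)
  exc <- model$arch$pop[ses$input_spikes$afferent] == 0
  g1 <- model$arch$group[ses$input_spikes$afferent] == 1
  z <- lowpass_trace(ses$input_spikes$time[exc & g1], 20e3, tau = 10)
  y <- lowpass_trace(ses$spikes, 20e3, tau = 250)
  keep <- seq_along(z) > 50000  # drop the 5 s burn-in
  offline <- pearson_cor(z[keep], y[keep])
  expect_equal(ses$C[1], offline, tolerance = 1e-6)
})
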