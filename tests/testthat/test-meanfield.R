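test_that("Hebbian fixed point is alpha_H / (2 tau_STDP) in Hz and stable", {
  fp <- hebbian_fixed_point(0.2, 20)
  expect_identical(fp$rate, 5)
  expect_identical(fp$stability, "stable")
  expect_identical(hebbian_fixed_point(0, 20)$rate, 0)
  expect_equal(hebbian_fixed_point(0.4, 20)$rate,
               2 * hebbian_fixed_point(0.2, 20)$rate)
})

test_that("anti-Hebbian threshold mirrors the same formula and is unstable", {
  th <- antihebbian_threshold(0.165, 20)
  expect_equal(th$rate, 4.125)
  expect_identical(th$stability, "unstable")
  expect_equal(antihebbian_threshold(0.2, 20)$rate,
               hebbian_fixed_point(0.2, 20)$rate)
})

test_that("reduced rate iterations drift toward/away from the fixed point", {
  up <- rate_drift(8, "hebbian", rho = 5)
  dn <- rate_drift(2, "hebbian", rho = 5)
  expect_true(all(diff(up) < 0))       # decreases toward 5
  expect_true(all(diff(dn) > 0))       # increases toward 5
  away_hi <- rate_drift(4.5, "anti_hebbian", rho = 4.125)
  away_lo <- rate_drift(3.8, "anti_hebbian", rho = 4.125)
  expect_true(all(diff(away_hi) > 0))  # above threshold: runs away upward
  expect_true(all(diff(away_lo) < 0))  # below threshold: collapses
})

test_that("scaling schedule closed forms match single-interval solutions", {
  sp <- scaling_params()
  eta <- sp$eta_s / sp$dt_ref
  # single LTD interval: exponential shrinkage
  out <- scaling_limit_weight(ltd_intervals = 5e5, ltp_intervals = numeric(0),
                              w0 = 0.7, y_ltd = 3, y_ltp = 0, params = sp)
  expect_equal(unname(out[1, "w_final"]), 0.7 * exp(-eta * 3 * 5e5),
               tolerance = 1e-12)
  # single LTP interval: linear growth
  out2 <- scaling_limit_weight(ltd_intervals = numeric(0), ltp_intervals = 2e5,
                               w0 = 0.7, y_ltd = 0, y_ltp = 4, params = sp)
  expect_equal(unname(out2[1, "w_final"]), 0.7 + eta * sp$w_Is * 4 * 2e5,
               tolerance = 1e-12)
  expect_error(scaling_limit_weight(numeric(0), numeric(0), 1), "empty")
  expect_error(scaling_limit_weight(c(1, 1, 1), 1, 1), "alternate")
})

test_that("long alternating schedules forget the initial weight", {
  sp <- scaling_params()
  set.seed(5)
  ltd <- rep(2e4, 200) * runif(200, 0.5, 1.5)
  ltp <- rep(2e4, 200) * runif(200, 0.5, 1.5)
  out <- scaling_limit_weight(ltd, ltp, w0 = c(0.1, 1.0),
                              y_ltd = 2.5, y_ltp = 2.5, params = sp)
  spread <- abs(diff(out[, "w_final"])) / mean(out[, "w_final"])
  expect_lt(spread, 0.01)
})

test_that("the spiking Hebbian loop settles near the mean-field setpoint", {
  # full-scale model at default parameters; the transient first minute is
  # excluded and the remaining 4 min averaged
  m <- isp_model("hebbian", scale = 1, seed = 1)
  tr <- train_inhibition(m, duration = 300e3, seed = 2)
  rate <- sum(tr$session$spikes > 60e3) / 240
  rho0 <- hebbian_fixed_point(m$hebbian$alpha_H, m$hebbian$tau_STDP)$rate
  expect_lt(abs(rate - rho0) / rho0, 0.2)
})

test_that("anti-Hebbian instability: frozen rate diverges, decaying rate freezes", {
  cfg <- default_config()
  cfg$plasticity$antihebbian$tau_aH <- 1e12  # effectively frozen learning rate
  # weak inhibition start: rate far above rho_1, coincidence dominates, so
  # anti-Hebbian weights must shrink (driving the rate still higher)
  m_hi <- isp_model("anti_hebbian", scale = 0.25, seed = 3, config = cfg,
                    w_IF = 0.3)
  s_hi <- simulate_session(m_hi, 30e3, plasticity = TRUE, seed = 4,
                           correlation = FALSE)
  expect_lt(mean(s_hi$weights[m_hi$arch$pop == 1]), 0.3 * 0.5)
  # strong inhibition start: rate below rho_1, lone-presynaptic potentiation
  # dominates, weights must grow (suppressing the rate further)
  m_lo <- isp_model("anti_hebbian", scale = 0.25, seed = 5, config = cfg,
                    w_IF = 3)
  s_lo <- simulate_session(m_lo, 30e3, plasticity = TRUE, seed = 6,
                           correlation = FALSE)
  expect_gt(mean(s_lo$weights[m_lo$arch$pop == 1]), 3)
  # with the default decaying learning rate the late weight drift vanishes
  m_dec <- isp_model("anti_hebbian", scale = 0.25, seed = 7, w_IF = 0.55)
  m_dec$antihebbian <- antihebbian_params(tau_aH = 5e3)  # decay within the run
  s_dec <- simulate_session(m_dec, 60e3, plasticity = TRUE, seed = 8,
                            correlation = FALSE, weights_every = 10e3)
  snaps <- s_dec$w_snapshots[, m_dec$arch$pop == 1, drop = FALSE]
  late_drift <- mean(abs(snaps[6, ] - snaps[5, ]))
  early_drift <- mean(abs(snaps[2, ] - snaps[1, ]))
  expect_lt(late_drift, early_drift / 10)
})
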