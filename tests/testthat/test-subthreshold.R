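test_that("input resistance matches the ideal RC value", {
  rec <- make_rc_record(R_mohm = 100, amps = seq(-100, -20, by = 20))
  expect_equal(input_resistance(rec), 100, tolerance = 1e-6)
  # single -100 pA sweep with -15 mV deflection -> 150 MOhm
  rec2 <- make_rc_record(R_mohm = 150, amps = -100)
  expect_equal(input_resistance(rec2), 150, tolerance = 1e-6)
  # positive-only record: undefined with reason
  rec3 <- make_rc_record(amps = c(20, 40))
  r <- input_resistance(rec3)
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "hyperpolarizing")
})

test_that("noisy input resistance agrees with a regression oracle", {
  set.seed(21)
  amps <- seq(-100, -20, by = 20)
  sweeps <- lapply(amps, function(a) {
    s <- make_rc_sweep(R_mohm = 150, I_pa = a)
    s$voltage <- s$voltage + rnorm(length(s$voltage), 0, 0.2)
    s
  })
  rec <- cell_record(sweeps, "noisy")
  rin <- input_resistance(rec)
  expect_equal(rin, 150, tolerance = 0.02)
  # independent oracle: least-squares slope of deflection vs current on the
  # same window means
  dv <- vapply(rec$sweeps, function(s) {
    t <- sweep_times(s)
    mean(s$voltage[t >= 900 & t < 1000]) - mean(s$voltage[t >= 100 & t < 200])
  }, numeric(1))
  slope <- 1000 * unname(coef(lm(dv ~ amps))[2])
  expect_equal(rin, slope, tolerance = 0.02)
})

test_that("membrane tau: closed form, multi-sweep mean, undefined case", {
  rec <- make_rc_record(tau_ms = 20, amps = -100)
  expect_equal(membrane_tau(rec), 20, tolerance = 0.05 / 20)
  # two sweeps with different true taus average to 12 ms
  s10 <- make_rc_sweep(tau_ms = 10, I_pa = -100)
  s14 <- make_rc_sweep(tau_ms = 14, I_pa = -80)
  rec2 <- cell_record(list(s10, s14), "two-tau")
  expect_equal(membrane_tau(rec2), 12, tolerance = 0.01)
  expect_true(is.na(membrane_tau(make_rc_record(amps = 20))))
})

test_that("resting Vm compensates holding current ohmically", {
  rec <- make_rc_record(E_mv = -65, amps = seq(-100, -20, by = 20))
  expect_equal(resting_vm(rec), -65, tolerance = 1e-9)
  # baseline -67 mV under -20 pA holding with Rin 100 -> rest -65
  rec2 <- make_rc_record(R_mohm = 100, E_mv = -65, holding = -20,
                         amps = seq(-100, -20, by = 20))
  expect_equal(sweep_times(rec2$sweeps[[1]])[1] + rec2$sweeps[[1]]$voltage[1],
               -67, tolerance = 1e-9)
  expect_equal(resting_vm(rec2), -65, tolerance = 1e-6)
})

test_that("sag ratio follows its amplitude-ratio definition", {
  # constructed trace: baseline -65, min -75, steady -74 -> 0.1
  s <- make_piecewise_sweep(
    times = c(0, 200, 230, 900, 1000, 1040, 1300),
    voltages = c(-65, -65, -75, -74, -74, -65, -65),
    amplitude_pa = -100)
  rec <- cell_record(list(s), "sag")
  expect_equal(sag_ratio(rec), 0.1, tolerance = 1e-3)
  # pure RC: min equals steady state -> 0
  expect_equal(sag_ratio(make_rc_record()), 0, tolerance = 2e-3)
  # no -100 pA sweep -> undefined with reason
  r <- sag_ratio(make_rc_record(amps = c(-80, -60)))
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "-100")
})

test_that("sag ratio matches the trace oracle on simulated h-current cells", {
  p <- membrane_params(C = 150, g_L = 8, E_L = -70, Delta_T = 0, g_h = 2,
                       a = 0, b = 0, noise_sd = 0)
  rec <- simulate_membrane(p, step_protocol(n_steps = 1))
  s <- rec$sweeps[[1]]
  t <- sweep_times(s)
  vb <- mean(s$voltage[t >= 100 & t < 200])
  vss <- mean(s$voltage[t >= 900 & t < 1000])
  vmin <- min(s$voltage[t >= 200 & t < 1000])
  oracle <- (vss - vmin) / (vb - vmin)
  expect_gt(oracle, 0.02)
  expect_equal(sag_ratio(rec), oracle, tolerance = 1e-6)
})

test_that("sag ratio increases monotonically with the h-conductance", {
  sags <- vapply(c(0, 1, 2, 4), function(gh) {
    p <- membrane_params(C = 150, g_L = 8, E_L = -70, Delta_T = 0,
                         g_h = gh, a = 0, b = 0, noise_sd = 0)
    sag_ratio(simulate_membrane(p, step_protocol(n_steps = 1)))
  }, numeric(1))
  expect_true(all(diff(sags) > 0))
  expect_equal(sags[1], 0, tolerance = 1e-3)
})

test_that("rebound features: clamping, constructed overshoot, h-current", {
  # monotone return to baseline: rebound clamped at 0
  rf <- rebound_features(make_rc_record())
  expect_equal(rf$rebound, 0, tolerance = 1e-6)
  # constructed overshoot peaking 3 mV above baseline, sag amplitude 1 mV
  s <- make_piecewise_sweep(
    times = c(0, 200, 230, 900, 1000, 1020, 1060, 1300),
    voltages = c(-65, -65, -75, -74, -74, -62, -65, -65),
    amplitude_pa = -100)
  rf2 <- rebound_features(cell_record(list(s), "ovr"))
  expect_equal(rf2$rebound, 3, tolerance = 1e-2)
  expect_equal(rf2$rebound_sag_ratio, 3, tolerance = 0.05)
  # simulated h-current cell: rebound > 0 and equal to the trace oracle
  p <- membrane_params(C = 150, g_L = 8, E_L = -70, Delta_T = 0, g_h = 3,
                       a = 0, b = 0, noise_sd = 0)
  rec <- simulate_membrane(p, step_protocol(n_steps = 1))
  s <- rec$sweeps[[1]]
  t <- sweep_times(s)
  vb <- mean(s$voltage[t >= 100 & t < 200])
  oracle <- max(s$voltage[t >= 1000 & t <= 1200]) - vb
  rf3 <- rebound_features(rec)
  expect_gt(rf3$rebound, 0)
  expect_equal(rf3$rebound, oracle, tolerance = 1e-4)
})

test_that("Rin and tau are invariant to vertical trace shifts", {
  rec <- make_rc_record(R_mohm = 120, tau_ms = 15)
  shifted <- shift_record(rec, 7.5)
  expect_equal(input_resistance(shifted), input_resistance(rec),
               tolerance = 1e-12)
  expect_equal(membrane_tau(shifted), membrane_tau(rec), tolerance = 1e-12)
})

test_that("passive cells show zero sag and rebound within noise tolerance", {
  # the sag minimum is a raw extremum, so its expectation under noise is the
  # extreme-value excursion of the stationary voltage sd (~ 3.5 sigma)
  p <- membrane_params(C = 180, g_L = 9, E_L = -67, Delta_T = 0, g_h = 0,
                       a = 0, b = 0, noise_sd = 0.05, seed = 31)
  rec <- simulate_membrane(p, step_protocol(n_steps = 3))
  expect_lt(sag_ratio(rec), 0.06)
  expect_lt(rebound_features(rec)$rebound, 0.8)
})

test_that("subthreshold_features returns one row with diagnostics", {
  sf <- subthreshold_features(make_rc_record(R_mohm = 100, tau_ms = 20))
  expect_equal(nrow(sf), 1)
  d <- attr(sf, "diagnostics")
  expect_equal(nrow(d), 5)
  # the exponential-fit tau cross-check agrees on ideal RC data
  expect_equal(mean(d$tau_fit), 20, tolerance = 0.02)
})
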