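test_that("steady-state model current reproduces closed-form anchor cases", {
  # pure leak at its reversal potential carries no current
  p <- channel_params(g_leak = 1, e_leak = -70,
                      lva = list(g_max = 0), hva = list(g_max = 0),
                      spike = list(g_na = 0))
  expect_equal(steady_state_model_current(p, -70), 0)
  # half-open channel at its V50: 20 nS * 0.5 * (V - E_K) = 500 pA
  p2 <- channel_params(g_leak = 0, e_k = -90,
                       lva = list(g_max = 20, v50 = -40, k = 5, b = 0),
                       hva = list(g_max = 0), spike = list(g_na = 0))
  expect_equal(steady_state_model_current(p2, -40), 20 * 0.5 * 50)
  # full default two-channel set at -20 mV: frozen 40-digit hand evaluation
  p3 <- channel_params()
  expect_equal(steady_state_model_current(p3, -20, include_na = FALSE),
               927.38839600047442874, tolerance = 1e-12)
  expect_equal(steady_state_model_current(p3, -20, include_na = TRUE),
               -794.47501481051285766, tolerance = 1e-12)
})

test_that("noise-free voltage-clamp families settle to the analytic steady state", {
  p <- quiet_params()
  fam <- simulate_vclamp_family(p)
  proto <- fam$protocol
  for (j in seq_along(proto$levels)) {
    v_true <- proto$levels[j] + proto$ljp
    got <- steady_state_current(family_trace(fam, j), proto$duration)
    want <- steady_state_model_current(p, v_true, include_na = FALSE)
    expect_lt(abs(got - want) / max(abs(want), 1), 1e-9)
  }
})

test_that("voltage-clamp simulation is a pure function of the seed", {
  p <- channel_params()
  a <- simulate_vclamp_family(p, seed = 17)
  b <- simulate_vclamp_family(p, seed = 17)
  expect_identical(a$sweeps, b$sweeps)
  c <- simulate_vclamp_family(p, seed = 18)
  expect_false(identical(a$sweeps, c$sweeps))
})

test_that("late-window averaging reduces noise like a standard error of the mean", {
  # 100 samples in the 1-ms window at 0.01-ms sampling with 5 pA noise:
  # the window mean should scatter with SD ~ 5/sqrt(100) across seeds
  p <- quiet_params()
  proto <- vclamp_protocol(levels = -40, sampling_interval = 0.01)
  means <- vapply(1:200, function(s) {
    fam <- simulate_vclamp_family(p, proto, seed = s, noise_sd = 5)
    steady_state_current(family_trace(fam, 1), proto$duration)
  }, numeric(1))
  expect_equal(sd(means), 5 / sqrt(100), tolerance = 0.25)
})

test_that("subthreshold current-clamp response matches the RC analytic solution", {
  p <- rc_params()  # tau 8 ms, R 200 MOhm, C 40 pF
  tr <- simulate_cclamp_trace(p, stim = list(amplitude = -10, onset = 20,
                                             duration = 100))
  t <- tr$time_ms
  vm <- ifelse(
    t < 20, -65,
    ifelse(t < 120,
           -65 - 2 * (1 - exp(-(t - 20) / 8)),
           -65 - 2 * (1 - exp(-100 / 8)) * exp(-(t - 120) / 8)))
  expect_lt(max(abs(tr$voltage_mV - vm)) / 2, 0.005)  # <= 0.5% of the 2-mV step
  pp <- passive_properties(tr)
  expect_equal(pp$tau_ms, 8, tolerance = 0.005)
  expect_equal(pp$r_in_MOhm, 200, tolerance = 0.005)
  expect_equal(pp$c_m_pF, 40, tolerance = 0.01)
})

test_that("zero current injection holds the membrane at rest", {
  p <- quiet_params()
  tr <- simulate_cclamp_trace(p, stim = list(amplitude = 0))
  expect_lt(max(abs(tr$voltage_mV - resting_potential(p))), 1e-6)
})

test_that("suprathreshold integration agrees with a 10x finer reference step", {
  p <- quiet_params()
  coarse <- simulate_cclamp_trace(p, stim = list(amplitude = 300),
                                  dt = 0.01, record_dt = 0.02)
  fine <- simulate_cclamp_trace(p, stim = list(amplitude = 300),
                                dt = 0.001, record_dt = 0.02)
  a <- detect_aps(coarse)
  b <- detect_aps(fine)
  expect_gte(nrow(a), 1)
  expect_equal(nrow(a), nrow(b))
  expect_lt(abs(a$peak_time_ms[1] - b$peak_time_ms[1]), 0.1)
  expect_lt(abs(a$peak_mV[1] - b$peak_mV[1]), 1)
  f <- ap_features(coarse, onset = 20)
  expect_gt(f$rise_rate, abs(f$repol_rate))
})

test_that("cohort generation is reproducible and respects the condition contract", {
  spec <- condition_spec("control", n_neurons = 3)
  a <- make_cohort(spec, seed = 5, include_cclamp = FALSE)
  b <- make_cohort(spec, seed = 5, include_cclamp = FALSE)
  expect_equal(nrow(a), 3)
  expect_identical(a$vclamp[[2]]$sweeps, b$vclamp[[2]]$sweeps)
  expect_identical(a$params, b$params)
  # embryo nesting: at most 6 neurons per embryo
  big <- make_cohort(condition_spec("control", n_neurons = 8), seed = 1,
                     include_cclamp = FALSE)
  expect_lte(max(table(big$embryo_id)), 6)
})

test_that("scaling down the LVA conductance strictly lowers current at -40 mV", {
  base <- quiet_params()
  scales <- c(0.4, 0.7, 1, 1.3)
  currents <- vapply(scales, function(s) {
    p <- base
    p$lva$g_max <- base$lva$g_max * s
    steady_state_model_current(p, -40, include_na = FALSE)
  }, numeric(1))
  expect_true(all(diff(currents) > 0))
})

test_that("BDNF preset encodes the treated/control conductance ratios", {
  spec <- nm_condition("BDNF")
  expect_equal(spec$scale_lva, 11.92 / 20.19)
  expect_equal(spec$scale_hva, 50.40 / 72.76)
  expect_equal(spec$n_neurons, 20L)
  expect_equal(nm_condition("control")$n_neurons, 16L)
})

test_that("invalid generator inputs are rejected", {
  expect_error(channel_params(c_m = 0), "c_m")
  expect_error(channel_params(lva = list(k = -2)), "k")
  expect_error(channel_params(noise_sd_current = -1), "noise")
  expect_error(condition_spec("control", scale_lva = 0), "multipliers")
  expect_error(condition_spec("control", n_neurons = 0), "n_neurons")
  expect_error(vclamp_protocol(levels = numeric()), "non-empty")
  expect_error(vclamp_protocol(duration = 5), "duration")
  expect_error(simulate_cclamp_trace(channel_params(),
                                     stim = list(amplitude = 10,
                                                 duration = -1)),
               "duration")
})
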