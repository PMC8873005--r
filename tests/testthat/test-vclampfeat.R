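passive_vc_trace <- function(c_m = 30, dv = 10, noise_sd = 0, seed = 1,
                             g_l = 2) {
  p <- neuron_params(g_na = 0, g_kd = 0, g_a = 0, g_m = 0, g_l = g_l,
                     c_m = c_m, noise_sd = noise_sd)
  proto <- protocol_spec("voltage_clamp_steps", holding = -70,
                         steps = -70 + dv, t_on = 0.05, t_off = 0.45,
                         duration = 0.5)
  simulate_voltage_clamp(p, proto, seed = seed)$traces[[1]]
}

test_that("capacitance is recovered exactly from a noise-free transient", {
  tr <- passive_vc_trace(c_m = 30, dv = 10)
  expect_lt(abs(estimate_capacitance(tr, 10, 0.05, 0.45) - 30) / 30, 0.01)
  tr2 <- passive_vc_trace(c_m = 47.5, dv = -20)
  expect_lt(abs(estimate_capacitance(tr2, -20, 0.05, 0.45) - 47.5) / 47.5, 0.01)
})

test_that("capacitance stays within 5% at 5 pA noise over 20 seeds", {
  est <- vapply(1:20, function(s) {
    tr <- passive_vc_trace(c_m = 30, dv = 10, noise_sd = 5, seed = s)
    estimate_capacitance(tr, 10, 0.05, 0.45)
  }, numeric(1))
  expect_true(all(abs(est - 30) / 30 < 0.05))
})

test_that("capacitance estimation rejects degenerate inputs", {
  tr <- passive_vc_trace()
  expect_error(estimate_capacitance(tr, 0, 0.05), "non-zero")
  flat <- trace(rnorm(5000, 0, 1), fs = 10000, kind = "current")
  expect_error(estimate_capacitance(flat, 10, 0.25), "transient")
})

test_that("capacitance estimate is invariant to active conductances", {
  proto <- vc_protocol()
  cap_for <- function(g_na, g_kd, g_a) {
    p <- neuron_params(c_m = 33, g_na = g_na, g_kd = g_kd, g_a = g_a,
                       g_m = 2, noise_sd = 0)
    vclamp_features(simulate_voltage_clamp(p, proto, seed = 1))$capacitance_pF
  }
  caps <- c(cap_for(0, 0, 0), cap_for(100, 30, 5), cap_for(300, 80, 15))
  expect_true(all(abs(caps - 33) / 33 < 0.02))
})

test_that("leak subtraction recovers and removes the linear leak", {
  p <- neuron_params(g_na = 0, g_kd = 0, g_a = 0, g_m = 0, g_l = 2,
                     e_l = -65, noise_sd = 0)
  ss <- simulate_voltage_clamp(p, vc_protocol(), seed = 1)
  sub <- subtract_leak(ss)
  leak <- attr(sub, "leak")
  expect_lt(abs(leak$g_ns - 2) / 2, 0.02)
  expect_lt(abs(leak$e_rev_mV - (-65)), 1)
  # pure-leak cell: post-transient samples ~ 0 everywhere after subtraction
  for (tr in blank_transient(sub, 1.5)$traces) {
    t <- trace_times(tr)
    late <- t >= 0.06 & t < 0.45
    expect_lt(max(abs(tr$samples[late])), 0.5)
  }
})

test_that("a constant offset current is absorbed by the leak fit", {
  p <- neuron_params(c_m = 30, g_na = 150, g_kd = 40, g_a = 8, g_m = 2,
                     noise_sd = 0)
  ss <- simulate_voltage_clamp(p, vc_protocol(), seed = 1)
  ss_off <- ss
  for (k in seq_along(ss_off$traces)) {
    ss_off$traces[[k]]$samples <- ss_off$traces[[k]]$samples + 35
  }
  iv0 <- extract_currents(blank_transient(subtract_leak(ss), 1.5))
  iv1 <- extract_currents(blank_transient(subtract_leak(ss_off), 1.5))
  expect_equal(iv1$na_peak_pA, iv0$na_peak_pA, tolerance = 1e-6)
  expect_equal(iv1$kslow_pA, iv0$kslow_pA, tolerance = 1e-6)
})

test_that("a static outward conductance appears in kslow, not na_peak", {
  proto <- vc_protocol()
  g <- 3
  e_k <- -90
  fs <- proto$fs
  n <- round(proto$duration * fs)
  t <- (seq_len(n) - 1) / fs
  traces <- lapply(proto$steps, function(v_cmd) {
    v <- ifelse(t >= proto$t_on & t < proto$t_off, v_cmd, proto$holding)
    trace(g * (v - e_k), fs = fs, kind = "current")
  })
  iv <- extract_currents(sweep_set(proto, traces))
  expect_equal(iv$kslow_pA, g * (proto$steps - e_k), tolerance = 1e-9)
  depol <- proto$steps >= -60
  expect_true(all(iv$na_peak_pA[depol] >= 0)) # nothing inward to find
})

test_that("Na peak is maximal at intermediate voltages and ~0 at E_Na", {
  p <- neuron_params(c_m = 30, g_na = 200, g_kd = 0, g_a = 0, g_m = 0,
                     g_l = 1, noise_sd = 0)
  proto <- protocol_spec("voltage_clamp_steps", holding = -70,
                         steps = seq(-90, 60, by = 10), t_on = 0.05,
                         t_off = 0.45, duration = 0.5)
  vf <- vclamp_features(simulate_voltage_clamp(p, proto, seed = 1))
  iv <- vf$iv
  i_max <- which.min(iv$na_peak_pA)
  expect_gt(iv$v_cmd_mV[i_max], -45)
  expect_lt(iv$v_cmd_mV[i_max], 10)
  at_ena <- iv$na_peak_pA[iv$v_cmd_mV == p$e_na]
  expect_lt(abs(at_ena), 0.02 * abs(min(iv$na_peak_pA)))
})

test_that("doubling g_A doubles the fast-K peak within 10%", {
  kf <- function(g_a) {
    p <- neuron_params(c_m = 30, g_na = 0, g_kd = 0, g_a = g_a, g_m = 0,
                       b_tau = 60, noise_sd = 0)
    vf <- vclamp_features(simulate_voltage_clamp(p, vc_protocol(), seed = 1))
    vf$iv$kfast_peak_pA[vf$iv$v_cmd_mV == 0]
  }
  expect_lt(abs(kf(10) / kf(5) - 2), 0.2)
})

test_that("measurement windows must lie inside the step", {
  p <- neuron_params(noise_sd = 0)
  ss <- simulate_voltage_clamp(p, vc_protocol(), seed = 1)
  expect_error(extract_currents(ss, na_window_ms = c(0.5, 600)), "windows")
})

test_that("leak fit requires at least two subthreshold steps", {
  p <- neuron_params(noise_sd = 0)
  proto <- protocol_spec("voltage_clamp_steps", holding = -70,
                         steps = c(-80, 0, 20), t_on = 0.05, t_off = 0.45,
                         duration = 0.5)
  ss <- simulate_voltage_clamp(p, proto, seed = 1)
  expect_error(subtract_leak(ss), "2 subthreshold")
})
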