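test_that("passive cell follows the RC closed form", {
  p <- neuron_params(g_na = 0, g_kd = 0, g_a = 0, g_m = 0, g_l = 2,
                     c_m = 30, noise_sd = 0)
  proto <- quick_cc_protocol(steps = 20)
  ss <- simulate_current_clamp(p, proto, seed = 1)
  tr <- ss$traces[[1]]
  t <- trace_times(tr)
  rest <- mean(tr$samples[t < proto$t_on])
  expect_lt(abs(rest - p$e_l), 0.01)
  # steady-state deflection dV = I / g_L = 10 mV
  plateau <- mean(tr$samples[t > proto$t_on + 0.15 & t < proto$t_off])
  expect_lt(abs(plateau - rest - 10) / 10, 0.01)
  # tau = C/g = 15 ms: at t_on + tau the response is 1 - 1/e of the step
  v_tau <- tr$samples[which.min(abs(t - (proto$t_on + 0.015)))]
  expect_lt(abs((v_tau - rest) - 10 * (1 - exp(-1))) / 10, 0.01)
})

test_that("zero-amplitude steps settle at the resting equilibrium", {
  p <- neuron_params(noise_sd = 0)
  proto <- protocol_spec("current_clamp_steps", steps = c(0, 0),
                         t_on = 0.05, t_off = 0.25, duration = 0.3)
  ss <- simulate_current_clamp(p, proto, seed = 1)
  for (tr in ss$traces) {
    late <- tr$samples[trace_times(tr) > 0.2]
    expect_lt(max(late) - min(late), 0.5)
  }
})

test_that("spike count on the noiseless trace matches a crossing counter", {
  p <- neuron_params(c_m = 25, g_na = 120, g_kd = 30, g_a = 8, g_m = 4,
                     noise_sd = 0)
  proto <- quick_cc_protocol(steps = 50)
  tr <- simulate_current_clamp(p, proto, seed = 1)$traces[[1]]
  n_cross <- crossing_count(tr$samples, 0)
  expect_gt(n_cross, 0)
  expect_equal(length(detect_spikes(tr)), n_cross)
})

test_that("current-clamp output is bit-identical for identical inputs", {
  p <- neuron_params(noise_sd = 2)
  proto <- quick_cc_protocol(steps = c(10, 30))
  a <- simulate_current_clamp(p, proto, seed = 42)
  b <- simulate_current_clamp(p, proto, seed = 42)
  expect_identical(a$traces[[1]]$samples, b$traces[[1]]$samples)
  expect_identical(a$traces[[2]]$samples, b$traces[[2]]$samples)
  c <- simulate_current_clamp(p, proto, seed = 43)
  expect_false(identical(a$traces[[1]]$samples, c$traces[[1]]$samples))
})

test_that("simulators reject invalid protocols and parameters", {
  p <- neuron_params()
  expect_error(simulate_current_clamp(p, vc_protocol()), "mode")
  expect_error(simulate_voltage_clamp(p, cc_protocol()), "mode")
  p_bad <- neuron_params()
  p_bad$r_s <- 0
  expect_error(simulate_voltage_clamp(p_bad, vc_protocol()), "r_s")
  expect_error(neuron_params(g_na = -1), "conductances")
  expect_error(neuron_params(c_m = 0), "c_m")
  expect_error(neuron_params(e_k = -50, e_l = -65), "e_k < e_l")
})

test_that("voltage clamp reproduces the ohmic leak exactly", {
  p <- neuron_params(g_na = 0, g_kd = 0, g_a = 0, g_m = 0, g_l = 2,
                     e_l = -65, c_m = 30, noise_sd = 0)
  proto <- vc_protocol()
  ss <- simulate_voltage_clamp(p, proto, seed = 1, include_transient = FALSE)
  for (k in seq_along(proto$steps)) {
    t <- trace_times(ss$traces[[k]])
    during <- t >= proto$t_on + 0.01 & t < proto$t_off
    expect_equal(unique(round(ss$traces[[k]]$samples[during], 9)),
                 p$g_l * (proto$steps[k] - p$e_l))
  }
})

test_that("clamp transient carries exactly Q = C dV of charge", {
  p <- neuron_params(g_na = 0, g_kd = 0, g_a = 0, g_m = 0, g_l = 2,
                     c_m = 30, noise_sd = 0)
  proto <- protocol_spec("voltage_clamp_steps", holding = -70, steps = -60,
                         t_on = 0.05, t_off = 0.45, duration = 0.5)
  tr <- simulate_voltage_clamp(p, proto, seed = 1)$traces[[1]]
  t <- trace_times(tr)
  leak <- p$g_l * (-60 - p$e_l)
  on <- t >= proto$t_on & t < proto$t_on + 0.02
  q <- sum(tr$samples[on] - leak) * 1000 / tr$fs # pA * ms = fC
  expect_lt(abs(q - p$c_m * 10) / (p$c_m * 10), 0.01)
})

test_that("doubling g_Na strictly deepens the peak inward current", {
  base <- list(c_m = 30, g_kd = 30, g_a = 5, g_m = 2, g_l = 1.5, noise_sd = 0)
  peak_at <- function(g_na) {
    p <- do.call(neuron_params, c(base, list(g_na = g_na)))
    ss <- simulate_voltage_clamp(p, vc_protocol(), seed = 1)
    min(vclamp_features(ss)$iv$na_peak_pA)
  }
  expect_lt(peak_at(200), peak_at(100))
})

test_that("synaptic generator obeys its contracts", {
  # empty process
  quiet <- simulate_synaptic_recording(synaptic_stats(rate_hz = 0),
                                       duration_s = 10, fs = 5000,
                                       noise_sd = 0, seed = 1)
  expect_equal(nrow(quiet$events), 0)
  expect_equal(unique(quiet$trace$samples), 0)

  # single event is peak-normalized to -A
  one <- simulate_synaptic_recording(synaptic_stats(rate_hz = 0.2,
                                                    amp_mean_pA = 30,
                                                    amp_cv = 0),
                                     duration_s = 10, fs = 10000,
                                     noise_sd = 0, seed = 5)
  expect_gt(nrow(one$events), 0)
  expect_lt(abs(min(one$trace$samples) + 30) / 30, 0.01)

  # Poisson count inside the central 99% interval at lambda = 0.5 Hz x 600 s
  lots <- simulate_synaptic_recording(synaptic_stats(rate_hz = 0.5),
                                      duration_s = 600, fs = 5000,
                                      noise_sd = 0, seed = 11)
  ci <- qpois(c(0.005, 0.995), 300)
  expect_gte(nrow(lots$events), ci[1])
  expect_lte(nrow(lots$events), ci[2])

  # contract errors
  expect_error(synaptic_stats(tau_rise_ms = 10, tau_decay_ms = 5), "tau_rise")
  expect_error(synaptic_stats(rate_hz = -1), "rates")
  expect_error(simulate_synaptic_recording(synaptic_stats(), duration_s = 10,
                                           fs = 1000), "resolve")
  expect_error(simulate_synaptic_recording(synaptic_stats(), duration_s = 0),
               "duration")

  # determinism
  a <- simulate_synaptic_recording(synaptic_stats(), 20, seed = 3)
  b <- simulate_synaptic_recording(synaptic_stats(), 20, seed = 3)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$events, b$events)
})
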