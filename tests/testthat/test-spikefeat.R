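test_that("constant traces contain no spikes", {
  tr <- trace(rep(-65, 5000), fs = 10000, kind = "voltage")
  expect_equal(detect_spikes(tr), numeric(0))
})

test_that("inserted stereotyped spikes are recovered within 1 ms", {
  truth <- c(0.1, 0.25, 0.4, 0.62, 0.85)
  tr <- make_spiky_trace(truth, duration_s = 1, noise_sd = 1, seed = 3)
  got <- detect_spikes(tr)
  expect_length(got, 5)
  expect_true(all(abs(got - truth) < 1e-3))
})

test_that("detector equals the brute-force oracle on random traces", {
  set.seed(202)
  for (i in 1:50) {
    n_sp <- sample(0:4, 1)
    times <- sort(runif(n_sp, 0.05, 0.25))
    if (length(times) > 1) times <- times[c(TRUE, diff(times) > 0.02)]
    tr <- make_spiky_trace(times, duration_s = 0.3, noise_sd = runif(1, 0, 2),
                           amp = runif(1, 60, 90), seed = i)
    expect_equal(detect_spikes(tr),
                 brute_force_spikes(tr$samples, tr$fs),
                 tolerance = 1e-12)
  }
})

test_that("triangular spike geometry is measured exactly", {
  # rise -45 -> +15 mV over 2 ms, symmetric fall; threshold -45
  fs <- 10000
  k <- round(2e-3 * fs)
  wave <- c(seq(-45, 15, length.out = k + 1), seq(15, -45, length.out = k + 1)[-1])
  v <- c(rep(-65, 500), seq(-65, -45, length.out = 100), wave,
         rep(-65, 1000))
  proto <- protocol_spec("current_clamp_steps", steps = 10, t_on = 0.02,
                         t_off = 0.15, duration = length(v) / fs)
  ss <- sweep_set(proto, list(trace(v, fs = fs, kind = "voltage")))
  feats <- first_spike_features(ss)
  expect_equal(feats$amplitude_mV, 60, tolerance = 0.05)
  expect_equal(feats$fwhm_ms, 2.0, tolerance = 0.05)
  expect_equal(feats$threshold_mV, -45, tolerance = 0.5)
})

test_that("Gaussian spike FWHM is 2.355 sigma within one sample", {
  fs <- 10000
  sigma_s <- 1e-3
  t <- seq(0, 0.2, by = 1 / fs)
  v <- -45 + 150 * exp(-(t - 0.1)^2 / (2 * sigma_s^2))
  proto <- protocol_spec("current_clamp_steps", steps = 10, t_on = 0.01,
                         t_off = 0.19, duration = 0.2 + 1 / fs)
  ss <- sweep_set(proto, list(trace(v, fs = fs, kind = "voltage")))
  feats <- first_spike_features(ss)
  expect_lt(abs(feats$fwhm_ms - 2.355), 0.1)
})

test_that("fAHP is the trough-minus-threshold, with sign", {
  # spike from threshold -45, then descent to -60 mV
  fs <- 10000
  k <- round(1e-3 * fs)
  wave <- c(seq(-45, 20, length.out = k), seq(20, -60, length.out = k),
            rep(-60, 200), seq(-60, -65, length.out = 50))
  v <- c(rep(-65, 300), seq(-65, -45, length.out = 60), wave, rep(-65, 300))
  proto <- protocol_spec("current_clamp_steps", steps = 10, t_on = 0.01,
                         t_off = 0.08, duration = length(v) / fs)
  ss <- sweep_set(proto, list(trace(v, fs = fs, kind = "voltage")))
  feats <- first_spike_features(ss)
  expect_equal(feats$fahp_mV, -15, tolerance = 0.5)
})

test_that("shape features are invariant to a constant voltage offset", {
  p <- neuron_params(c_m = 25, g_na = 120, g_kd = 30, g_a = 8, g_m = 4,
                     noise_sd = 0)
  ss <- simulate_current_clamp(p, quick_cc_protocol(steps = 50), seed = 1)
  f0 <- first_spike_features(ss)
  ss_shift <- ss
  ss_shift$traces[[1]]$samples <- ss$traces[[1]]$samples + 7
  f1 <- first_spike_features(ss_shift)
  expect_equal(f1$amplitude_mV, f0$amplitude_mV, tolerance = 1e-9)
  expect_equal(f1$fwhm_ms, f0$fwhm_ms, tolerance = 1e-9)
  expect_equal(f1$fahp_mV, f0$fahp_mV, tolerance = 1e-9)
  expect_equal(f1$threshold_mV, f0$threshold_mV + 7, tolerance = 1e-9)
})

test_that("excitability summary follows its definitions", {
  # five sweeps with known spike counts on steps 0..20 pA
  counts <- c(0, 0, 2, 5, 7)
  steps <- c(0, 5, 10, 15, 20)
  fs <- 10000
  traces <- lapply(counts, function(k) {
    times <- if (k > 0) seq(0.12, 0.35, length.out = k) else numeric(0)
    make_spiky_trace(times, fs = fs, duration_s = 0.5, noise_sd = 0)
  })
  proto <- protocol_spec("current_clamp_steps", steps = steps, t_on = 0.1,
                         t_off = 0.4, duration = 0.5)
  es <- excitability_summary(sweep_set(proto, traces))
  expect_equal(es$total_evoked, 14)
  expect_equal(es$max_per_step, 7)
  expect_equal(es$rheobase_pA, 10)
  expect_equal(es$per_step[[1]]$n_spikes, counts)

  # empty case
  quiet <- sweep_set(proto, lapply(steps, function(s) {
    trace(rep(-65, fs / 2), fs = fs, kind = "voltage")
  }))
  es0 <- excitability_summary(quiet)
  expect_equal(es0$total_evoked, 0)
  expect_equal(es0$max_per_step, 0)
  expect_true(is.na(es0$rheobase_pA))
  expect_true(is.na(first_spike_features(quiet)$fwhm_ms))
})

test_that("spikes outside the stimulus window are not counted as evoked", {
  tr <- make_spiky_trace(c(0.05, 0.2, 0.45), duration_s = 0.5)
  proto <- protocol_spec("current_clamp_steps", steps = 10, t_on = 0.1,
                         t_off = 0.4, duration = 0.5)
  es <- excitability_summary(sweep_set(proto, list(tr)))
  expect_equal(es$total_evoked, 1)
})

test_that("detector-based summary equals ground truth on simulator sweeps", {
  p <- neuron_params(c_m = 25, g_na = 120, g_kd = 30, g_a = 8, g_m = 4,
                     noise_sd = 0)
  proto <- cc_protocol()
  ss <- simulate_current_clamp(p, proto, seed = 1)
  es <- excitability_summary(ss)
  truth <- vapply(ss$traces, function(tr) {
    t <- trace_times(tr)
    in_step <- t >= proto$t_on & t <= proto$t_off
    crossing_count(tr$samples[in_step], 0)
  }, numeric(1))
  expect_equal(es$per_step[[1]]$n_spikes, truth)
})
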