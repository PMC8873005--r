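kernel_peak_delay_s <- function(tau_rise_ms = 2, tau_decay_ms = 10) {
  tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms) *
    log(tau_decay_ms / tau_rise_ms) / 1000
}

match_sets <- function(detected_s, truth_s, tol_s = 0.005) {
  recall <- if (length(truth_s) > 0) {
    mean(vapply(truth_s, function(t) any(abs(detected_s - t) < tol_s),
                logical(1)))
  } else NA_real_
  precision <- if (length(detected_s) > 0) {
    mean(vapply(detected_s, function(t) any(abs(truth_s - t) < tol_s),
                logical(1)))
  } else NA_real_
  list(recall = recall, precision = precision)
}

test_that("a flat noise-free trace yields no events", {
  tr <- trace(rep(-5, 5 * 5000), fs = 5000, kind = "current")
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 0)
})

test_that("detection hits the stated operating point on ground truth", {
  rec <- simulate_synaptic_recording(synaptic_stats(rate_hz = 0.5,
                                                    amp_mean_pA = 30),
                                     duration_s = 100, fs = 5000,
                                     noise_sd = 2, seed = 21)
  ev <- detect_events(rec$trace)
  truth <- rec$events$time_s + kernel_peak_delay_s()
  m <- match_sets(ev$time_s, truth)
  expect_gte(m$recall, 0.95)
  expect_gte(m$precision, 0.95)
  expect_lt(abs(mean(ev$amplitude_pA) - mean(rec$events$amplitude_pA)) /
              mean(rec$events$amplitude_pA), 0.1)
})

test_that("detection is invariant to a constant holding current", {
  rec <- simulate_synaptic_recording(synaptic_stats(rate_hz = 0.5,
                                                    amp_mean_pA = 30),
                                     duration_s = 30, fs = 5000,
                                     noise_sd = 2, seed = 4)
  ev0 <- detect_events(rec$trace)
  shifted <- rec$trace
  shifted$samples <- shifted$samples - 120
  ev1 <- detect_events(shifted)
  expect_equal(ev1$time_s, ev0$time_s)
  expect_equal(ev1$amplitude_pA, ev0$amplitude_pA, tolerance = 1e-9)
})

test_that("detector agrees with a matched-filter oracle on clean traces", {
  for (s in 1:20) {
    # well-separated unambiguous events
    set.seed(1000 + s)
    n_ev <- sample(3:6, 1)
    onsets <- sort(runif(n_ev, 1, 9))
    onsets <- onsets[c(TRUE, diff(onsets) > 0.3)]
    fs <- 5000
    dur <- 10
    x <- rnorm(dur * fs, 0, 1.5)
    t_ms <- (seq_len(round(0.08 * fs)) - 1) / fs * 1000
    kern <- (exp(-t_ms / 10) - exp(-t_ms / 2))
    kern <- kern / max(kern)
    for (on in onsets) {
      i0 <- round(on * fs) + 1
      idx <- i0:(i0 + length(kern) - 1)
      x[idx] <- x[idx] - runif(1, 25, 40) * kern
    }
    tr <- trace(x, fs = fs, kind = "current")
    got <- detect_events(tr)$time_s
    oracle <- matched_filter_events(tr)
    expect_equal(length(got), length(onsets))
    expect_equal(length(oracle), length(onsets))
    expect_true(all(abs(sort(got) - sort(oracle)) < 3e-3))
  }
})

test_that("event statistics follow their definitions", {
  ev <- tibble::tibble(amplitude_pA = c(10, 20, 30))
  st <- event_statistics(ev, 60)
  expect_equal(st$mean_amplitude_pA, 20)
  expect_equal(st$rate_hz, 0.05)
  expect_equal(st$ecdf(20), 2 / 3)
  expect_equal(st$ecdf(max(ev$amplitude_pA)), 1)

  st0 <- event_statistics(tibble::tibble(amplitude_pA = numeric(0)), 60)
  expect_equal(st0$rate_hz, 0)
  expect_true(is.na(st0$mean_amplitude_pA))
  expect_error(event_statistics(ev, 0), "duration")
})

test_that("recovered event rate sits in the 99% Poisson interval", {
  rec <- simulate_synaptic_recording(synaptic_stats(rate_hz = 0.5,
                                                    amp_mean_pA = 30),
                                     duration_s = 600, fs = 5000,
                                     noise_sd = 2, seed = 31)
  ev <- detect_events(rec$trace)
  ci <- qpois(c(0.005, 0.995), 0.5 * 600)
  expect_gte(nrow(ev), ci[1])
  expect_lte(nrow(ev), ci[2])
})

test_that("amplitude scaling moves the ECDF axis and not the rate", {
  ev <- tibble::tibble(amplitude_pA = c(12, 18, 25, 40))
  st1 <- event_statistics(ev, 100)
  st2 <- event_statistics(dplyr::mutate(ev, amplitude_pA = amplitude_pA * 3),
                          100)
  expect_equal(st2$rate_hz, st1$rate_hz)
  for (q in c(12, 18, 25, 40)) {
    expect_equal(st2$ecdf(3 * q), st1$ecdf(q))
  }
})

test_that("burst segmentation follows its definition", {
  # events every 10 s: all gaps exceed the ISI threshold
  b0 <- detect_bursts(seq(0, 90, by = 10), 100)
  expect_equal(b0$n_bursts, 0)

  # 5 events at 50 ms gaps: one burst of 0.2 s
  b1 <- detect_bursts(seq(1, by = 0.05, length.out = 5), 10)
  expect_equal(b1$n_bursts, 1)
  expect_equal(b1$bursts$duration_s, 0.2)
  expect_equal(b1$bursts$n_events, 5L)

  expect_error(detect_bursts(c(3, 1, 2), 10), "sorted")
})

test_that("burst metrics recover the generated epochs", {
  # ~20 burst epochs of dense events on a sparse background
  rec <- simulate_synaptic_recording(
    synaptic_stats(rate_hz = 0.05, amp_mean_pA = 30, burst_rate_hz = 0.1,
                   burst_event_rate_hz = 40, burst_duration_s = 0.3),
    duration_s = 200, fs = 5000, noise_sd = 0, seed = 17)
  n_true <- nrow(rec$epochs)
  expect_gt(n_true, 10)
  bu <- detect_bursts(rec$events$time_s, 200)
  expect_lte(abs(bu$n_bursts - n_true) / n_true, 0.1)
  # true duration: span of the events inside each epoch
  spans <- vapply(split(rec$events$time_s[rec$events$source == "burst"],
                        rec$events$burst_id[rec$events$source == "burst"]),
                  function(tt) diff(range(tt)), numeric(1))
  expect_lte(abs(bu$mean_duration_s - mean(spans)) / mean(spans), 0.2)
})

test_that("bursts, interburst intervals and edge gaps partition the recording", {
  set.seed(5)
  times <- sort(c(runif(30, 0, 100),
                  unlist(lapply(runif(5, 10, 90), function(s) {
                    s + cumsum(rexp(8, 40))
                  }))))
  dur <- 100
  bu <- detect_bursts(times, dur)
  if (bu$n_bursts >= 1) {
    covered <- sum(bu$bursts$duration_s) + sum(bu$interburst_intervals_s) +
      bu$bursts$start_s[1] + (dur - bu$bursts$end_s[bu$n_bursts])
    expect_equal(covered, dur, tolerance = 1e-9)
  }
})
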