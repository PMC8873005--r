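# Independent oracles and fixture builders used across the suite.

# Literal per-sample implementation of the spike definition: exhaustive
# scan of all dV/dt up-crossings, peak validation within 5 ms, then
# refractory merging. Kept deliberately naive (sample-by-sample loop).
brute_force_spikes <- function(v, fs, dvdt_thresh = 10, min_peak_mV = -10,
                               refractory_ms = 2) {
  n <- length(v)
  dvdt <- numeric(n - 1)
  for (i in seq_len(n - 1)) dvdt[i] <- (v[i + 1] - v[i]) * fs / 1000
  win <- max(1, round(5e-3 * fs))
  peaks <- integer(0)
  for (i in seq_len(n - 1)) {
    prev <- if (i == 1) -Inf else dvdt[i - 1]
    if (dvdt[i] >= dvdt_thresh && prev < dvdt_thresh) {
      w <- i:min(i + win, n)
      pk <- w[1]
      for (k in w) if (v[k] > v[pk]) pk <- k
      if (v[pk] >= min_peak_mV) peaks <- c(peaks, pk)
    }
  }
  peaks <- sort(unique(peaks))
  gap <- max(1, round(refractory_ms / 1000 * fs))
  kept <- integer(0)
  for (p in peaks) {
    if (length(kept) == 0 || p - kept[length(kept)] >= gap) kept <- c(kept, p)
  }
  (kept - 1) / fs
}

# Count upward crossings of a fixed voltage level (independent spike
# counter for noiseless excitable traces).
crossing_count <- function(v, level = 0) {
  sum(v[-1] >= level & v[-length(v)] < level)
}

# Brute-force two-sample KS statistic: sup |F1 - F2| over the pooled
# sample points.
brute_force_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  f1 <- vapply(pts, function(x) mean(a <= x), numeric(1))
  f2 <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(f1 - f2))
}

# Matched-filter EPSC oracle: normalized cross-correlation with the
# known biexponential template at every lag, thresholded, then local
# maxima separated by a dead time. Returns peak times (s).
matched_filter_events <- function(tr, tau_rise_ms = 2, tau_decay_ms = 10,
                                  corr_min = 0.8, amp_min_pA = 8,
                                  dead_ms = 20) {
  fs <- tr$fs
  x <- tr$samples - stats::median(tr$samples)
  t_ms <- (seq_len(ceiling(6 * tau_decay_ms / 1000 * fs)) - 1) / fs * 1000
  tmpl <- -(exp(-t_ms / tau_decay_ms) - exp(-t_ms / tau_rise_ms))
  tmpl <- tmpl / sqrt(sum(tmpl^2))
  m <- length(tmpl)
  n <- length(x)
  score <- amp <- numeric(n - m)
  for (i in seq_len(n - m)) {
    seg <- x[i:(i + m - 1)]
    seg0 <- seg - mean(seg)
    ss <- sqrt(sum(seg0^2))
    if (ss == 0) next
    score[i] <- sum(seg0 * (tmpl - mean(tmpl))) /
      (ss * sqrt(sum((tmpl - mean(tmpl))^2)))
    amp[i] <- -min(seg)
  }
  cand <- which(score >= corr_min & amp >= amp_min_pA)
  if (length(cand) == 0) return(numeric(0))
  dead <- round(dead_ms / 1000 * fs)
  kept <- integer(0)
  for (i in cand[order(-score[cand])]) {
    if (length(kept) == 0 || all(abs(kept - i) >= dead)) kept <- c(kept, i)
  }
  onsets <- sort(kept)
  # report the peak (trace minimum) within the template span
  vapply(onsets, function(i) {
    w <- i:min(i + m - 1, n)
    (w[which.min(x[w])] - 1) / fs
  }, numeric(1))
}

# Voltage trace with stereotyped spike waveforms inserted at known times.
make_spiky_trace <- function(spike_times_s, fs = 10000, duration_s = 1,
                             baseline = -65, noise_sd = 0, amp = 80,
                             seed = 1) {
  n <- round(duration_s * fs)
  set.seed(seed)
  v <- rep(baseline, n) + stats::rnorm(n, 0, noise_sd)
  half_ms <- 1
  k <- round(half_ms / 1000 * fs)
  wave <- c(seq(0, amp, length.out = k + 1), seq(amp, 0, length.out = k + 1)[-1])
  spike_times_s <- spike_times_s[is.finite(spike_times_s)]
  for (ts in spike_times_s) {
    i0 <- round(ts * fs) + 1 - k
    idx <- i0:(i0 + length(wave) - 1)
    sel <- idx >= 1 & idx <= n
    v[idx[sel]] <- v[idx[sel]] + wave[sel]
  }
  trace(v, fs = fs, kind = "voltage")
}

# Fixed-statistics sample: n values with exactly the requested mean and
# SEM (affine transform of a centred base sample).
sample_with_stats <- function(mean, sem, n, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  x <- as.numeric(scale(x)) # mean 0, sd 1
  mean + x * sem * sqrt(n)
}

quick_cc_protocol <- function(steps = 20, fs = 10000) {
  protocol_spec("current_clamp_steps", holding = 0, steps = steps,
                t_on = 0.1, t_off = 0.4, duration = 0.5, fs = fs)
}
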