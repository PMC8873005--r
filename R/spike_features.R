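#' Detect action potentials on a voltage trace
#'
#' A spike is an upward crossing of the dV/dt threshold whose voltage
#' reaches `min_peak_mV` within 5 ms; the spike time is the voltage peak
#' in that window. Events with peaks closer than `refractory_ms` are
#' merged (the earlier peak is kept).
#'
#' @param tr A voltage [trace()].
#' @param dvdt_thresh dV/dt threshold, mV/ms.
#' @param min_peak_mV Minimum peak voltage for a valid spike, mV.
#' @param refractory_ms Minimum separation between spike peaks, ms.
#'
#' @return Numeric vector of spike peak times (s), ordered.
#' @export
detect_spikes <- function(tr, dvdt_thresh = 10, min_peak_mV = -10,
                          refractory_ms = 2) {
  stopifnot(inherits(tr, "ck_trace"))
  if (tr$kind != "voltage") stop("detect_spikes needs a voltage trace", call. = FALSE)
  v <- tr$samples
  n <- length(v)
  if (n < 2L) stop("trace too short", call. = FALSE)
  if (tr$fs < 2000) {
    stop("sampling rate below 2 kHz: insufficient resolution for spike detection",
         call. = FALSE)
  }
  idx <- spike_peak_indices(v, tr$fs, dvdt_thresh, min_peak_mV, refractory_ms)
  tr$t0 + (idx - 1) / tr$fs
}

# Shared core returning peak sample indices.
spike_peak_indices <- function(v, fs, dvdt_thresh, min_peak_mV, refractory_ms) {
  n <- length(v)
  dvdt <- diff(v) * fs / 1000 # mV/ms, dvdt[i] between samples i and i+1
  up <- which(dvdt >= dvdt_thresh & c(-Inf, dvdt[-length(dvdt)]) < dvdt_thresh)
  if (length(up) == 0L) return(integer(0))
  win <- max(1L, round(5e-3 * fs))
  peaks <- vapply(up, function(i) {
    w <- i:min(i + win, n)
    pk <- w[which.max(v[w])]
    if (v[pk] >= min_peak_mV) pk else NA_integer_
  }, integer(1))
  peaks <- sort(unique(peaks[!is.na(peaks)]))
  if (length(peaks) == 0L) return(integer(0))
  gap <- max(1L, round(refractory_ms / 1000 * fs))
  keep <- peaks[1]
  for (p in peaks[-1]) {
    if (p - keep[length(keep)] >= gap) keep <- c(keep, p)
  }
  keep
}

# Threshold-crossing sample for the spike peaking at peak_idx: the first
# sample of the last upward dV/dt crossing before the peak.
threshold_index <- function(v, fs, peak_idx, dvdt_thresh) {
  dvdt <- diff(v) * fs / 1000
  upto <- max(1L, peak_idx - 1L)
  seg <- dvdt[seq_len(upto)]
  cross <- which(seg >= dvdt_thresh & c(-Inf, seg[-length(seg)]) < dvdt_thresh)
  if (length(cross) == 0L) return(NA_integer_)
  cross[length(cross)]
}

interp_crossing_time <- function(v, fs, i_below, i_above, level) {
  # linear interpolation of the time where v crosses `level` between two
  # adjacent samples (indices in trace order)
  frac <- (level - v[i_below]) / (v[i_above] - v[i_below])
  ((i_below - 1) + frac * (i_above - i_below)) / fs
}

#' Shape features of the rheobase ("first") spike
#'
#' Selects the first spike on the lowest-amplitude step that evokes any
#' spike (ties broken by sweep order) and measures: threshold (voltage at
#' the last upward dV/dt crossing before the peak), amplitude (peak minus
#' threshold), FWHM (time spent above threshold + amplitude/2, with linear
#' interpolation at the half crossings), and the fast
#' afterhyperpolarization (minimum voltage after the spike falls back
#' below threshold, within `fahp_window_ms`, truncated at the next spike's
#' threshold crossing; reported as trough minus threshold, negative).
#'
#' @param ss A current-clamp [sweep_set()].
#' @param dvdt_thresh,min_peak_mV,refractory_ms Spike-detection settings,
#'   see [detect_spikes()].
#' @param fahp_window_ms Post-spike search window for the fAHP trough, ms.
#'
#' @return A one-row tibble: `rheobase_pA`, `sweep`, `threshold_mV`,
#'   `peak_mV`, `amplitude_mV`, `fwhm_ms`, `fahp_mV`, `peak_time_s`.
#'   All-`NA` feature columns if no sweep spikes.
#' @export
first_spike_features <- function(ss, dvdt_thresh = 10, min_peak_mV = -10,
                                 refractory_ms = 2, fahp_window_ms = 20) {
  stopifnot(inherits(ss, "ck_sweep_set"))
  proto <- ss$protocol
  empty <- tibble::tibble(rheobase_pA = NA_real_, sweep = NA_integer_,
                          threshold_mV = NA_real_, peak_mV = NA_real_,
                          amplitude_mV = NA_real_, fwhm_ms = NA_real_,
                          fahp_mV = NA_real_, peak_time_s = NA_real_)
  ord <- order(proto$steps)
  rheo_sweep <- NA_integer_
  spike_times <- NULL
  for (k in ord) {
    tt <- detect_spikes(ss$traces[[k]], dvdt_thresh, min_peak_mV, refractory_ms)
    tt <- tt[tt >= proto$t_on & tt <= proto$t_off]
    if (length(tt) > 0) {
      rheo_sweep <- k
      spike_times <- tt
      break
    }
  }
  if (is.na(rheo_sweep)) return(empty)
  tr <- ss$traces[[rheo_sweep]]
  v <- tr$samples
  fs <- tr$fs
  n <- length(v)
  peak_idx <- round((spike_times[1] - tr$t0) * fs) + 1L
  i_thr <- threshold_index(v, fs, peak_idx, dvdt_thresh)
  if (is.na(i_thr)) return(empty)
  thr <- v[i_thr]
  amp <- v[peak_idx] - thr
  half <- thr + amp / 2

  # FWHM with interpolated half crossings around the peak
  left <- peak_idx
  while (left > 1L && v[left - 1L] >= half) left <- left - 1L
  right <- peak_idx
  while (right < n && v[right + 1L] >= half) right <- right + 1L
  t_left <- if (left > 1L) interp_crossing_time(v, fs, left - 1L, left, half) else (left - 1) / fs
  t_right <- if (right < n) interp_crossing_time(v, fs, right + 1L, right, half) else (right - 1) / fs
  fwhm_ms <- (t_right - t_left) * 1000

  # fAHP: trough after V falls back below threshold
  nxt_start <- n
  if (length(spike_times) >= 2) {
    nxt_peak <- round((spike_times[2] - tr$t0) * fs) + 1L
    nxt_thr <- threshold_index(v, fs, nxt_peak, dvdt_thresh)
    if (!is.na(nxt_thr)) nxt_start <- min(nxt_start, nxt_thr)
  }
  below <- which(v[peak_idx:nxt_start] < thr)
  fahp <- NA_real_
  if (length(below) > 0) {
    i_fall <- peak_idx + below[1] - 1L
    i_end <- min(i_fall + round(fahp_window_ms / 1000 * fs), nxt_start)
    fahp <- min(v[i_fall:i_end]) - thr
  }
  tibble::tibble(rheobase_pA = proto$steps[rheo_sweep], sweep = rheo_sweep,
                 threshold_mV = thr, peak_mV = v[peak_idx],
                 amplitude_mV = amp, fwhm_ms = fwhm_ms, fahp_mV = fahp,
                 peak_time_s = spike_times[1])
}

#' Excitability summary of a current-clamp step family
#'
#' Counts evoked spikes per step (restricted to the stimulus window) and
#' summarizes: total over all steps, maximum on any step, and rheobase
#' (smallest step amplitude evoking at least one spike; ties broken by
#' sweep order).
#'
#' @inheritParams first_spike_features
#'
#' @return A one-row tibble: `total_evoked`, `max_per_step`,
#'   `rheobase_pA` (`NA` if no sweep spikes) and a `per_step` list column
#'   holding the per-sweep count table.
#' @export
excitability_summary <- function(ss, dvdt_thresh = 10, min_peak_mV = -10,
                                 refractory_ms = 2) {
  stopifnot(inherits(ss, "ck_sweep_set"))
  proto <- ss$protocol
  if (proto$mode != "current_clamp_steps") {
    stop("excitability_summary needs a current-clamp sweep set", call. = FALSE)
  }
  counts <- vapply(ss$traces, function(tr) {
    tt <- detect_spikes(tr, dvdt_thresh, min_peak_mV, refractory_ms)
    sum(tt >= proto$t_on & tt <= proto$t_off)
  }, numeric(1))
  per_step <- tibble::tibble(sweep = seq_along(counts),
                             step_pA = proto$steps, n_spikes = counts)
  ord <- order(proto$steps)
  spiking <- ord[counts[ord] >= 1]
  rheo <- if (length(spiking) > 0) proto$steps[spiking[1]] else NA_real_
  tibble::tibble(total_evoked = sum(counts), max_per_step = max(counts),
                 rheobase_pA = rheo, per_step = list(per_step))
}
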