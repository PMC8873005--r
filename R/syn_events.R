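#' Detect spontaneous EPSCs on a gap-free current trace
#'
#' Baseline and noise are estimated robustly (sliding median of the
#' trace, sliding MAD of the residual). Candidate events are inward
#' local minima of the lightly smoothed residual exceeding `k_sd` times
#' the local noise SD (local minima rather than threshold runs, so
#' overlapping events inside a burst are still resolved), separated by
#' at least `min_separation_ms`. A candidate is accepted only if its
#' kinetics look synaptic: 10-90% rise time and log-linear decay
#' constant inside the stated bounds, decay slower than rise, and a
#' decay segment that is actually exponential (fit R-squared at least `decay_r2_min`). The amplitude is the local-baseline-to-peak
#' magnitude, reported positive.
#'
#' @param tr A current [trace()] (gap-free voltage-clamp recording).
#' @param k_sd Detection threshold in units of the local noise SD.
#' @param rise_bounds_ms Acceptable 10-90% rise-time range, ms.
#' @param decay_bounds_ms Acceptable decay-constant range, ms.
#' @param window_s Sliding window for the median/MAD baseline, s.
#' @param min_separation_ms Minimum separation between event peaks, ms.
#' @param smooth_ms Moving-average window used for the kinetic
#'   measurements, ms.
#' @param decay_r2_min Minimum R-squared of the log-linear decay fit.
#'
#' @return A tibble of accepted events: `time_s` (peak time),
#'   `amplitude_pA` (positive), `rise_ms`, `decay_ms`, sorted by time.
#' @export
detect_events <- function(tr, k_sd = 3, rise_bounds_ms = c(0.5, 5),
                          decay_bounds_ms = c(3, 50), window_s = 1,
                          min_separation_ms = 5, smooth_ms = 0.6,
                          decay_r2_min = 0.75) {
  stopifnot(inherits(tr, "ck_trace"))
  if (tr$kind != "current") stop("detect_events needs a current trace", call. = FALSE)
  fs <- tr$fs
  x <- tr$samples
  n <- length(x)
  if (n < 2L * round(window_s * fs)) {
    stop("trace shorter than twice the sliding window", call. = FALSE)
  }
  # sliding median baseline and sliding MAD noise, computed on a ~500 Hz
  # decimated grid (a 1 s window does not need full resolution) and
  # interpolated back
  dec_by <- max(1L, floor(fs / 500))
  idx <- seq(1L, n, by = dec_by)
  k_win <- round(window_s * fs / dec_by)
  if (k_win %% 2 == 0) k_win <- k_win + 1L
  base_d <- stats::runmed(x[idx], k_win, endrule = "median")
  base <- stats::approx(idx, base_d, seq_len(n), rule = 2)$y
  r <- x - base
  # short moving average for peak finding and kinetics; keeps the
  # biexponential shape but knocks the sample-to-sample noise down
  sm <- max(3L, round(smooth_ms / 1000 * fs))
  if (sm %% 2 == 0) sm <- sm + 1L
  rs <- as.numeric(stats::filter(r, rep(1 / sm, sm), sides = 2))
  pad <- (sm - 1L) %/% 2L
  rs[seq_len(pad)] <- r[seq_len(pad)]
  rs[(n - pad + 1L):n] <- r[(n - pad + 1L):n]
  noise_d <- 1.4826 * stats::runmed(abs(rs[idx]), k_win, endrule = "median")
  noise <- stats::approx(idx, noise_d, seq_len(n), rule = 2)$y
  noise <- pmax(noise, 1e-12)
  hit <- rs < -k_sd * noise
  if (!any(hit)) {
    return(tibble::tibble(time_s = numeric(0), amplitude_pA = numeric(0),
                          rise_ms = numeric(0), decay_ms = numeric(0)))
  }
  loc_min <- c(FALSE, rs[2:(n - 1)] <= rs[1:(n - 2)] &
                 rs[2:(n - 1)] < rs[3:n], FALSE)
  peaks <- which(hit & loc_min)
  if (length(peaks) == 0L) peaks <- which.min(rs)
  gap <- round(min_separation_ms / 1000 * fs)
  span <- round(0.1 * fs) # one decay-fit window
  # depth-first separation: a candidate close to an already-kept (deeper)
  # peak is a distinct event only if the residual rebounded toward
  # baseline in between; otherwise it is a shoulder of the same event
  peaks <- peaks[order(rs[peaks])]
  kept <- integer(0)
  for (p in peaks) {
    near <- kept[abs(kept - p) < span]
    ok <- TRUE
    for (q in near) {
      if (abs(q - p) < gap) {
        ok <- FALSE
        break
      }
      io <- (min(p, q) + 1L):(max(p, q) - 1L)
      if (max(rs[io]) <= 0.5 * rs[p]) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, p)
  }
  peaks <- sort(kept)

  pre_n <- round(0.02 * fs) # local-baseline window, 20 ms before the event
  out <- purrr::map_dfr(seq_along(peaks), function(j) {
    p <- peaks[j]
    lo <- max(1L, p - pre_n)
    b_loc <- stats::median(rs[lo:max(lo, p - round(0.005 * fs))])
    amp <- b_loc - rs[p]
    if (amp <= 0) return(NULL)
    # 10-90% rise time: last crossings before the peak on the smoothed
    # residual
    lev10 <- b_loc - 0.1 * amp
    lev90 <- b_loc - 0.9 * amp
    i <- p
    while (i > 1L && rs[i - 1L] <= lev90) i <- i - 1L
    t90 <- if (i > 1L) interp_crossing_time(rs, fs, i - 1L, i, lev90) else (i - 1) / fs
    while (i > 1L && rs[i - 1L] <= lev10) i <- i - 1L
    t10 <- if (i > 1L) interp_crossing_time(rs, fs, i - 1L, i, lev10) else (i - 1) / fs
    rise <- (t90 - t10) * 1000
    # decay constant: log-linear fit down to 20% recovery, truncated
    # where the decay envelope rebounds (an overlapping next event)
    d_end <- min(n, p + round(0.1 * fs))
    dec <- b_loc - rs[p:d_end]
    rebound <- which(dec > cummin(dec) + 0.35 * amp)
    if (length(rebound) > 0) dec <- dec[seq_len(max(rebound[1] - 1L, 2L))]
    stop_at <- which(dec < 0.2 * amp)
    if (length(stop_at) > 0) dec <- dec[seq_len(max(stop_at[1] - 1L, 2L))]
    dec <- dec[dec > 0]
    decay <- NA_real_
    r2 <- 0
    if (length(dec) >= 4L) {
      ld <- log(dec)
      ii <- seq_along(ld)
      slope <- stats::cov(ii, ld) / stats::var(ii)
      r2 <- suppressWarnings(stats::cor(ii, ld)^2)
      if (is.finite(slope) && slope < 0) decay <- -1 / slope * 1000 / fs
    }
    ok <- is.finite(rise) && rise >= rise_bounds_ms[1] && rise <= rise_bounds_ms[2] &&
      is.finite(decay) && decay >= decay_bounds_ms[1] && decay <= decay_bounds_ms[2] &&
      decay > rise && is.finite(r2) && r2 >= decay_r2_min
    if (!ok) return(NULL)
    tibble::tibble(time_s = tr$t0 + (p - 1) / fs, amplitude_pA = amp,
                   rise_ms = rise, decay_ms = decay)
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(time_s = numeric(0), amplitude_pA = numeric(0),
                          rise_ms = numeric(0), decay_ms = numeric(0)))
  }
  dplyr::arrange(out, .data$time_s)
}

#' Summary statistics of a synaptic event list
#'
#' @param events A tibble with an `amplitude_pA` column (e.g. from
#'   [detect_events()]); may be empty.
#' @param duration_s Recording duration, s (> 0).
#'
#' @return A list of class `ck_event_stats`: `n`, `rate_hz`,
#'   `mean_amplitude_pA`, `sem_amplitude_pA`, and `ecdf` (right-continuous
#'   empirical CDF of the amplitudes; `NULL` when empty).
#' @export
event_statistics <- function(events, duration_s) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  amps <- events$amplitude_pA
  n <- length(amps)
  structure(list(
    n = n,
    rate_hz = n / duration_s,
    mean_amplitude_pA = if (n > 0) mean(amps) else NA_real_,
    sem_amplitude_pA = if (n > 1) stats::sd(amps) / sqrt(n) else NA_real_,
    ecdf = if (n > 0) stats::ecdf(amps) else NULL
  ), class = "ck_event_stats")
}

#' @export
print.ck_event_stats <- function(x, ...) {
  cat(sprintf("<ck_event_stats> n = %d, rate = %.3g Hz, amplitude %.3g pA\n",
              x$n, x$rate_hz, x$mean_amplitude_pA))
  invisible(x)
}

#' @export
glance.ck_event_stats <- function(x, ...) {
  tibble::tibble(n = x$n, rate_hz = x$rate_hz,
                 mean_amplitude_pA = x$mean_amplitude_pA,
                 sem_amplitude_pA = x$sem_amplitude_pA)
}

#' Segment event times into network bursts
#'
#' A burst is a maximal run of at least `min_events` consecutive events
#' whose inter-event intervals are all at most `max_isi_s`. Burst
#' duration is last minus first event time of the run; the burst rate is
#' bursts per recording duration; interburst intervals are the gaps
#' between consecutive burst end and start.
#'
#' @param event_times Sorted event times, s.
#' @param duration_s Recording duration, s.
#' @param max_isi_s Maximum within-burst inter-event interval, s.
#' @param min_events Minimum number of events per burst.
#'
#' @return A list of class `ck_burst_summary`: `bursts` (tibble:
#'   `start_s`, `end_s`, `duration_s`, `n_events`), `n_bursts`,
#'   `burst_rate_hz`, `mean_duration_s`, `interburst_intervals_s`,
#'   `mean_interburst_s`, `recording_s`.
#' @export
detect_bursts <- function(event_times, duration_s, max_isi_s = 0.1,
                          min_events = 3) {
  if (is.unsorted(event_times)) stop("event times must be sorted", call. = FALSE)
  n <- length(event_times)
  bursts <- tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                           duration_s = numeric(0), n_events = integer(0))
  if (n >= min_events) {
    linked <- diff(event_times) <= max_isi_s
    runs <- rle(linked)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(runs$values)) {
      n_ev <- runs$lengths[j] + 1L # intervals -> events
      if (n_ev >= min_events) {
        i0 <- starts[j]
        i1 <- ends[j] + 1L
        bursts <- dplyr::bind_rows(bursts, tibble::tibble(
          start_s = event_times[i0], end_s = event_times[i1],
          duration_s = event_times[i1] - event_times[i0],
          n_events = n_ev))
      }
    }
  }
  ibi <- if (nrow(bursts) >= 2) {
    bursts$start_s[-1] - bursts$end_s[-nrow(bursts)]
  } else numeric(0)
  structure(list(
    bursts = bursts,
    n_bursts = nrow(bursts),
    burst_rate_hz = nrow(bursts) / duration_s,
    mean_duration_s = if (nrow(bursts) > 0) mean(bursts$duration_s) else NA_real_,
    interburst_intervals_s = ibi,
    mean_interburst_s = if (length(ibi) > 0) mean(ibi) else NA_real_,
    recording_s = duration_s
  ), class = "ck_burst_summary")
}

#' @export
print.ck_burst_summary <- function(x, ...) {
  cat(sprintf("<ck_burst_summary> %d bursts (%.3g Hz), mean duration %.3g s\n",
              x$n_bursts, x$burst_rate_hz, x$mean_duration_s))
  invisible(x)
}

#' @export
tidy.ck_burst_summary <- function(x, ...) x$bursts

#' @export
glance.ck_burst_summary <- function(x, ...) {
  tibble::tibble(n_bursts = x$n_bursts, burst_rate_hz = x$burst_rate_hz,
                 mean_duration_s = x$mean_duration_s,
                 mean_interburst_s = x$mean_interburst_s)
}
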