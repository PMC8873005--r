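#' Estimate whole-cell capacitance from a charging transient
#'
#' Integrates the above-leak capacitive transient after a voltage step:
#' the post-transient steady (leak) level is subtracted, the transient is
#' summed from the step onset until it decays to 5% of its peak, and the
#' remaining exponential tail (decay constant fitted log-linearly on the
#' decay) is added analytically. Capacitance is the total charge divided
#' by the step size: `C (pF) = Q (fC) / dV (mV)`.
#'
#' @param tr A current [trace()] containing a step-onset transient.
#' @param dv_mV Voltage step size, mV (non-zero).
#' @param t_on_s Step onset time, s.
#' @param t_off_s Step offset time, s (end of the steady window; defaults
#'   to the end of the trace).
#'
#' @return Capacitance in pF (scalar).
#' @export
estimate_capacitance <- function(tr, dv_mV, t_on_s, t_off_s = NULL) {
  stopifnot(inherits(tr, "ck_trace"))
  if (tr$kind != "current") stop("need a current trace", call. = FALSE)
  if (dv_mV == 0) stop("dv_mV must be non-zero", call. = FALSE)
  fs <- tr$fs
  dt_ms <- 1000 / fs
  t <- trace_times(tr)
  x <- tr$samples
  if (is.null(t_off_s)) t_off_s <- t[length(t)] + 1 / fs
  pre <- x[t < t_on_s]
  if (length(pre) < 2L) stop("no pre-onset baseline available", call. = FALSE)
  step_idx <- which(t >= t_on_s & t < t_off_s)
  if (length(step_idx) < 10L) stop("step window too short", call. = FALSE)
  late <- step_idx[t[step_idx] >= t_on_s + 0.5 * (t_off_s - t_on_s)]
  steady <- stats::median(x[late])
  trans <- x[step_idx] - steady
  sgn <- sign(dv_mV)
  u <- sgn * trans # positive-going transient
  search <- which(t[step_idx] <= t_on_s + 5e-3)
  pk <- search[which.max(u[search])]
  noise <- stats::mad(pre - stats::median(pre))
  if (!is.finite(u[pk]) || u[pk] <= 0 || (noise > 0 && u[pk] < 5 * noise)) {
    stop("no detectable charging transient", call. = FALSE)
  }
  after_pk <- u[pk:length(u)]
  below <- which(after_pk < 0.05 * u[pk])
  cut <- if (length(below) > 0) pk + below[1] - 2L else length(u) # last kept
  q_meas <- sum(u[1:cut]) * dt_ms # pA * ms = fC
  # geometric tail beyond the 5% cutoff, from the fitted decay ratio
  tail_q <- 0
  dec <- u[pk:cut]
  dec <- dec[dec > 0]
  if (length(dec) >= 2L) {
    fit <- stats::lm(log(dec) ~ seq_along(dec))
    r <- exp(stats::coef(fit)[2])
    if (is.finite(r) && r > 0 && r < 1) {
      tail_q <- u[cut] * dt_ms * r / (1 - r)
    }
  }
  unname((q_meas + tail_q) / abs(dv_mV))
}

#' Fit and subtract the linear leak from a voltage-clamp family
#'
#' Fits `I = g (V - E)` on the post-transient steady currents of the
#' subthreshold (hyperpolarized) steps and subtracts the predicted leak,
#' including the holding-potential baseline, from every sweep.
#'
#' @param ss A voltage-clamp [sweep_set()].
#' @param subthreshold_max_mV Steps at or below this command potential are
#'   treated as passive and used for the fit (need at least 2).
#'
#' @return The leak-subtracted `ck_sweep_set`, with the fitted leak model
#'   in `attr(, "leak")` (`g_ns`, `e_rev_mV`, `intercept_pA`).
#' @export
subtract_leak <- function(ss, subthreshold_max_mV = -60) {
  stopifnot(inherits(ss, "ck_sweep_set"))
  proto <- ss$protocol
  if (proto$mode != "voltage_clamp_steps") {
    stop("subtract_leak needs a voltage-clamp sweep set", call. = FALSE)
  }
  sub <- which(proto$steps <= subthreshold_max_mV)
  if (length(sub) < 2L) {
    stop("need at least 2 subthreshold steps for the leak fit", call. = FALSE)
  }
  steady <- vapply(sub, function(k) {
    tr <- ss$traces[[k]]
    t <- trace_times(tr)
    late <- t >= proto$t_on + 0.7 * (proto$t_off - proto$t_on) & t < proto$t_off
    stats::median(tr$samples[late])
  }, numeric(1))
  fit <- stats::lm(steady ~ proto$steps[sub])
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  out <- ss
  for (k in seq_along(ss$traces)) {
    tr <- ss$traces[[k]]
    t <- trace_times(tr)
    v_cmd <- ifelse(t >= proto$t_on & t < proto$t_off,
                    proto$steps[k], proto$holding)
    out$traces[[k]]$samples <- tr$samples - (a + b * v_cmd)
  }
  attr(out, "leak") <- list(g_ns = b, e_rev_mV = -a / b, intercept_pA = a)
  out
}

#' Blank the capacitive transients of a voltage-clamp family
#'
#' Replaces samples within `blank_ms` of the step onset and offset with a
#' linear interpolation across the blanked gap, the usual prerequisite to
#' peak-current measurement. With the default series resistance and
#' capacitance the transient decay constant is ~0.3 ms, so 1.5 ms (5
#' decay constants) removes it to <1%.
#'
#' @param ss A voltage-clamp [sweep_set()].
#' @param blank_ms Blanking window after each command jump, ms.
#' @return The blanked `ck_sweep_set` (leak attribute preserved).
#' @export
blank_transient <- function(ss, blank_ms = 0.5) {
  stopifnot(inherits(ss, "ck_sweep_set"))
  proto <- ss$protocol
  for (k in seq_along(ss$traces)) {
    tr <- ss$traces[[k]]
    t <- trace_times(tr)
    for (chg in c(proto$t_on, proto$t_off)) {
      idx <- which(t >= chg & t < chg + blank_ms / 1000)
      if (length(idx) == 0) next
      lo <- max(1L, idx[1] - 1L)
      hi <- min(length(tr$samples), idx[length(idx)] + 1L)
      tr$samples[idx] <- tr$samples[lo] +
        (tr$samples[hi] - tr$samples[lo]) * (idx - lo) / (hi - lo)
    }
    ss$traces[[k]] <- tr
  }
  ss
}

#' Extract peak sodium and potassium currents per command voltage
#'
#' On a leak-subtracted, transient-blanked family: the sodium peak is the
#' current minimum in an early window, the fast potassium peak the
#' maximum in an early-outward window, and the slow potassium current the
#' mean over the last part of the step. All windows are relative to the
#' step onset (offset for the slow window) and configurable.
#'
#' @param ss A leak-subtracted voltage-clamp [sweep_set()] (see
#'   [subtract_leak()], [blank_transient()]).
#' @param na_window_ms Early inward-search window, ms post-onset.
#' @param kfast_window_ms Early outward-search window, ms post-onset.
#' @param kslow_last_ms Averaging window before step offset, ms.
#'
#' @return A tibble with one row per command step: `v_cmd_mV`,
#'   `na_peak_pA` (<= 0 expected), `kfast_peak_pA`, `kslow_pA`; the leak
#'   model of the input (if any) is carried in `attr(, "leak")`.
#' @export
extract_currents <- function(ss, na_window_ms = c(0.5, 10),
                             kfast_window_ms = c(2, 25),
                             kslow_last_ms = 50) {
  stopifnot(inherits(ss, "ck_sweep_set"))
  proto <- ss$protocol
  step_ms <- (proto$t_off - proto$t_on) * 1000
  if (max(na_window_ms, kfast_window_ms, kslow_last_ms) > step_ms) {
    stop("measurement windows extend beyond the step", call. = FALSE)
  }
  rows <- purrr::map_dfr(seq_along(ss$traces), function(k) {
    tr <- ss$traces[[k]]
    t_ms <- (trace_times(tr) - proto$t_on) * 1000
    in_na <- t_ms >= na_window_ms[1] & t_ms <= na_window_ms[2]
    in_kf <- t_ms >= kfast_window_ms[1] & t_ms <= kfast_window_ms[2]
    in_ks <- t_ms >= step_ms - kslow_last_ms & t_ms < step_ms
    tibble::tibble(v_cmd_mV = proto$steps[k],
                   na_peak_pA = min(tr$samples[in_na]),
                   kfast_peak_pA = max(tr$samples[in_kf]),
                   kslow_pA = mean(tr$samples[in_ks]))
  })
  attr(rows, "leak") <- attr(ss, "leak")
  rows
}

#' Full voltage-clamp feature set for one cell
#'
#' Convenience wrapper: estimates capacitance from the most
#' hyperpolarized subthreshold step of the raw family, then leak-subtracts,
#' blanks the transients and extracts the I-V table.
#'
#' @inheritParams extract_currents
#' @inheritParams subtract_leak
#' @param blank_ms Transient blanking window, ms.
#' @return A list of class `ck_vclamp_features`: `capacitance_pF`, `iv`
#'   (tibble from [extract_currents()]), `leak`.
#' @export
vclamp_features <- function(ss, subthreshold_max_mV = -60, blank_ms = 1.5,
                            na_window_ms = c(0.5, 10),
                            kfast_window_ms = c(2, 25), kslow_last_ms = 50) {
  proto <- ss$protocol
  sub <- which(proto$steps <= subthreshold_max_mV &
                 proto$steps != proto$holding)
  cap <- NA_real_
  if (length(sub) > 0) {
    k <- sub[which.max(abs(proto$steps[sub] - proto$holding))]
    cap <- tryCatch(
      estimate_capacitance(ss$traces[[k]], proto$steps[k] - proto$holding,
                           proto$t_on, proto$t_off),
      error = function(e) NA_real_)
  }
  clean <- blank_transient(subtract_leak(ss, subthreshold_max_mV), blank_ms)
  iv <- extract_currents(clean, na_window_ms, kfast_window_ms, kslow_last_ms)
  structure(list(capacitance_pF = cap, iv = iv, leak = attr(iv, "leak")),
            class = "ck_vclamp_features")
}

#' @export
print.ck_vclamp_features <- function(x, ...) {
  cat(sprintf("<ck_vclamp_features> C = %.1f pF, leak %.2f nS; %d command steps\n",
              x$capacitance_pF, x$leak$g_ns %||% NA, nrow(x$iv)))
  invisible(x)
}
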