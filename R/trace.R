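#' Construct a single recording trace
#'
#' A trace is one uniformly sampled channel: membrane potential in current
#' clamp (`kind = "voltage"`, mV) or membrane current in voltage clamp
#' (`kind = "current"`, pA).
#'
#' @param samples Numeric vector of sample values.
#' @param fs Sampling rate in Hz.
#' @param kind `"voltage"` or `"current"`.
#' @param unit Physical unit; must be `"mV"` for voltage and `"pA"` for
#'   current traces. Defaults to the unit implied by `kind`.
#' @param t0 Start time of the first sample, seconds.
#'
#' @return An object of class `ck_trace`.
#' @export
#' @examples
#' tr <- trace(rep(-65, 1000), fs = 10000, kind = "voltage")
#' trace_duration(tr)
trace <- function(samples, fs, kind = c("voltage", "current"),
                  unit = NULL, t0 = 0) {
  kind <- match.arg(kind)
  default_unit <- switch(kind, voltage = "mV", current = "pA")
  if (is.null(unit)) unit <- default_unit
  if (!identical(unit, default_unit)) {
    stop("unit '", unit, "' inconsistent with kind '", kind, "'", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("samples must be a non-empty numeric vector", call. = FALSE)
  }
  structure(
    list(kind = kind, unit = unit, fs = as.numeric(fs), t0 = as.numeric(t0),
         samples = as.numeric(samples)),
    class = "ck_trace"
  )
}

#' @export
print.ck_trace <- function(x, ...) {
  cat(sprintf("<ck_trace> %s (%s), %d samples @ %g kHz, %.3f s\n",
              x$kind, x$unit, length(x$samples), x$fs / 1000,
              trace_duration(x)))
  invisible(x)
}

#' Sample times of a trace
#'
#' @param x A `ck_trace`.
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "ck_trace"))
  x$t0 + (seq_along(x$samples) - 1L) / x$fs
}

#' Trace duration in seconds
#' @param x A `ck_trace`.
#' @export
trace_duration <- function(x) {
  stopifnot(inherits(x, "ck_trace"))
  length(x$samples) / x$fs
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trace into a long tibble
#'
#' @param x A `ck_trace`.
#' @param ... Unused.
#' @return A tibble with columns `time_s` and `value`.
#' @export
tidy.ck_trace <- function(x, ...) {
  tibble::tibble(time_s = trace_times(x), value = x$samples)
}

#' Describe a stimulus protocol
#'
#' Captures the stimulus behind a family of sweeps: a holding level with a
#' rectangular step per sweep, or a gap-free (no stimulus) recording.
#'
#' @param mode `"current_clamp_steps"`, `"voltage_clamp_steps"` or
#'   `"gap_free"`.
#' @param holding Holding level: pA in current clamp, mV in voltage clamp.
#' @param steps Ordered vector of step amplitudes (pA or mV, absolute step
#'   level relative to zero for current clamp injections, absolute command
#'   potential for voltage clamp). Ignored for `gap_free`.
#' @param t_on,t_off Step onset/offset times in seconds.
#' @param duration Sweep duration in seconds.
#' @param fs Acquisition sampling rate in Hz.
#'
#' @return An object of class `ck_protocol`.
#' @export
protocol_spec <- function(mode = c("current_clamp_steps", "voltage_clamp_steps",
                                   "gap_free"),
                          holding = 0, steps = numeric(), t_on = 0.05,
                          t_off = 0.45, duration = 0.5, fs = 10000) {
  mode <- match.arg(mode)
  if (mode != "gap_free") {
    if (length(steps) < 1L) stop("step modes need a non-empty step list", call. = FALSE)
    if (!(t_on < t_off && t_off < duration)) {
      stop("need t_on < t_off < duration", call. = FALSE)
    }
  }
  structure(
    list(mode = mode, holding = as.numeric(holding), steps = as.numeric(steps),
         t_on = t_on, t_off = t_off, duration = duration, fs = fs),
    class = "ck_protocol"
  )
}

#' @export
print.ck_protocol <- function(x, ...) {
  if (x$mode == "gap_free") {
    cat(sprintf("<ck_protocol> gap-free, %.1f s @ %g kHz\n", x$duration, x$fs / 1000))
  } else {
    cat(sprintf("<ck_protocol> %s: %d steps [%g..%g], %g-%g ms, hold %g, %g kHz\n",
                x$mode, length(x$steps), min(x$steps), max(x$steps),
                x$t_on * 1000, x$t_off * 1000, x$holding, x$fs / 1000))
  }
  invisible(x)
}

#' Bundle sweeps from one protocol into a sweep set
#'
#' @param protocol A [protocol_spec()].
#' @param traces List of [trace()] objects, one per step, sharing `fs` and
#'   duration.
#' @param cell_id Cell identifier string.
#' @param genotype Condition label, e.g. `"control"` or `"mutant"`.
#' @param week Week in culture (numeric).
#'
#' @return An object of class `ck_sweep_set`.
#' @export
sweep_set <- function(protocol, traces, cell_id = "cell",
                      genotype = NA_character_, week = NA_real_) {
  stopifnot(inherits(protocol, "ck_protocol"))
  if (protocol$mode != "gap_free" &&
      length(traces) != length(protocol$steps)) {
    stop("need one trace per step amplitude", call. = FALSE)
  }
  fs <- vapply(traces, function(tr) tr$fs, numeric(1))
  ns <- vapply(traces, function(tr) length(tr$samples), numeric(1))
  if (length(unique(fs)) != 1L || length(unique(ns)) != 1L) {
    stop("all traces must share sampling rate and length", call. = FALSE)
  }
  structure(
    list(protocol = protocol, traces = traces, cell_id = cell_id,
         genotype = genotype, week = week),
    class = "ck_sweep_set"
  )
}

#' @export
print.ck_sweep_set <- function(x, ...) {
  cat(sprintf("<ck_sweep_set> %s (%s, week %s): %d sweeps\n",
              x$cell_id, x$genotype, format(x$week), length(x$traces)))
  print(x$protocol)
  invisible(x)
}

#' Tidy a sweep set into a long tibble
#'
#' @param x A `ck_sweep_set`.
#' @param ... Unused.
#' @return A tibble with columns `sweep`, `step`, `time_s`, `value`.
#' @export
tidy.ck_sweep_set <- function(x, ...) {
  steps <- if (x$protocol$mode == "gap_free") rep(NA_real_, length(x$traces)) else x$protocol$steps
  purrr::imap_dfr(x$traces, function(tr, i) {
    tibble::tibble(sweep = i, step = steps[[i]],
                   time_s = trace_times(tr), value = tr$samples)
  })
}
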