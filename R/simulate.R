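#' Simulate a current-clamp step family
#'
#' Integrates the single-compartment conductance model (see
#' [neuron_params()]) for each step of a current-clamp protocol. The
#' membrane is first settled for 200 ms at the holding current (noise
#' off), so every sweep starts from the resting equilibrium. Gaussian
#' current noise is drawn per integration step. Identical
#' `(params, protocol, seed)` give bit-identical output.
#'
#' @param params A [neuron_params()] object.
#' @param protocol A [protocol_spec()] with mode `current_clamp_steps`.
#'   Step amplitudes are injected currents in pA (holding current applied
#'   outside the step window).
#' @param seed Integer seed for the noise process.
#' @param dt_ms Integration step, ms (must divide the sample period;
#'   default 0.025 ms).
#' @param cell_id,genotype,week Labels attached to the returned sweep set.
#'
#' @return A [sweep_set()] of voltage traces, one per step.
#' @export
#' @examples
#' p <- neuron_params(g_na = 0, g_kd = 0, g_a = 0, g_l = 2, c_m = 30)
#' proto <- protocol_spec("current_clamp_steps", steps = 20,
#'                        t_on = 0.1, t_off = 0.4, duration = 0.5)
#' ss <- simulate_current_clamp(p, proto, seed = 1)
simulate_current_clamp <- function(params, protocol, seed = 1,
                                   dt_ms = 0.025, cell_id = "cell",
                                   genotype = NA_character_, week = NA_real_) {
  stopifnot(inherits(params, "ck_neuron_params"), inherits(protocol, "ck_protocol"))
  if (protocol$mode != "current_clamp_steps") {
    stop("protocol mode must be current_clamp_steps", call. = FALSE)
  }
  sample_ms <- 1000 / protocol$fs
  stride <- round(sample_ms / dt_ms)
  if (abs(stride * dt_ms - sample_ms) > 1e-9) {
    stop("dt_ms must divide the sample period 1/fs", call. = FALSE)
  }
  pp <- pack_params(params)
  n_steps <- round(protocol$duration * 1000 / dt_ms)
  step_t <- (seq_len(n_steps) - 1L) * dt_ms / 1000 # time of each dt step, s
  in_step <- step_t >= protocol$t_on & step_t < protocol$t_off

  # settle at the holding current so sweeps start at rest
  settle_n <- round(200 / dt_ms)
  s0 <- hh_steady_state(params$e_l, pp)
  settled <- hh_integrate_cc(pp, s0, dt_ms,
                             rep(protocol$holding, settle_n),
                             numeric(0), settle_n)$state

  traces <- with_seed(seed, lapply(protocol$steps, function(amp) {
    i_inj <- ifelse(in_step, amp, protocol$holding)
    noise <- if (params$noise_sd > 0) {
      stats::rnorm(n_steps, 0, params$noise_sd)
    } else numeric(0)
    v <- hh_integrate_cc(pp, settled, dt_ms, i_inj, noise, stride)$v
    trace(v, fs = protocol$fs, kind = "voltage")
  }))
  sweep_set(protocol, traces, cell_id = cell_id, genotype = genotype,
            week = week)
}

# Gate trajectories at a fixed command potential: closed-form exponential
# relaxation from `state` toward the steady state at v, evaluated at times
# t_ms (ms, relative to segment start). Returns the ionic current (pA) and
# the end-of-segment state.
vclamp_segment <- function(params, pp, state, v, t_ms, seg_ms) {
  gt <- hh_gate_table(v, pp)
  relax <- function(x0, xinf, tau, t) xinf + (x0 - xinf) * exp(-t / tau)
  m <- relax(state[2], gt[1, "m_inf"], gt[1, "tau_m"], t_ms)
  h <- relax(state[3], gt[1, "h_inf"], gt[1, "tau_h"], t_ms)
  n <- relax(state[4], gt[1, "n_inf"], gt[1, "tau_n"], t_ms)
  a <- relax(state[5], gt[1, "a_inf"], gt[1, "tau_a"], t_ms)
  b <- relax(state[6], gt[1, "b_inf"], gt[1, "tau_b"], t_ms)
  p_g <- relax(state[7], gt[1, "p_inf"], gt[1, "tau_p"], t_ms)
  i <- params$g_na * m^3 * h * (v - params$e_na) +
    params$g_kd * n^4 * (v - params$e_k) +
    params$g_a * a * b * (v - params$e_k) +
    params$g_m * p_g * (v - params$e_k) +
    params$g_l * (v - params$e_l)
  end <- c(v,
           relax(state[2], gt[1, "m_inf"], gt[1, "tau_m"], seg_ms),
           relax(state[3], gt[1, "h_inf"], gt[1, "tau_h"], seg_ms),
           relax(state[4], gt[1, "n_inf"], gt[1, "tau_n"], seg_ms),
           relax(state[5], gt[1, "a_inf"], gt[1, "tau_a"], seg_ms),
           relax(state[6], gt[1, "b_inf"], gt[1, "tau_b"], seg_ms),
           relax(state[7], gt[1, "p_inf"], gt[1, "tau_p"], seg_ms))
  list(i = i, state = end)
}

# Capacitive charging transient for a command jump of dv_mV at time
# chg_ms, as bin-averaged samples: each sample carries exactly the charge
# delivered during its sample interval, so the discrete integral of the
# transient equals C * dV regardless of sampling rate.
cap_transient <- function(t_ms, sample_ms, c_m, r_s, dv_mV, chg_ms) {
  tau <- r_s * c_m / 1000 # MOhm * pF = ns -> ms
  lo <- pmax(t_ms, chg_ms)
  hi <- t_ms + sample_ms
  out <- numeric(length(t_ms))
  live <- hi > chg_ms
  out[live] <- c_m * dv_mV *
    (exp(-(lo[live] - chg_ms) / tau) - exp(-(hi[live] - chg_ms) / tau)) /
    sample_ms
  out
}

#' Simulate a voltage-clamp step family
#'
#' Command potentials are imposed instantaneously; gating variables relax
#' exponentially toward their steady state at the commanded potential
#' (the closed-form solution of the gating ODEs at fixed voltage), and
#' the recorded current is the sum of ionic currents, the leak, and a
#' capacitive charging transient at each command jump with total charge
#' `C_m * dV` and decay constant `R_s * C_m`. Inward current is negative.
#'
#' @inheritParams simulate_current_clamp
#' @param protocol A [protocol_spec()] with mode `voltage_clamp_steps`;
#'   `steps` are absolute command potentials in mV, `holding` the holding
#'   potential in mV.
#' @param include_transient Add the capacitive transient (requires
#'   `r_s > 0`).
#'
#' @return A [sweep_set()] of current traces, one per command step.
#' @export
simulate_voltage_clamp <- function(params, protocol, seed = 1,
                                   include_transient = TRUE,
                                   cell_id = "cell",
                                   genotype = NA_character_, week = NA_real_) {
  stopifnot(inherits(params, "ck_neuron_params"), inherits(protocol, "ck_protocol"))
  if (protocol$mode != "voltage_clamp_steps") {
    stop("protocol mode must be voltage_clamp_steps", call. = FALSE)
  }
  if (include_transient && params$r_s <= 0) {
    stop("r_s must be > 0 when the capacitive transient is requested",
         call. = FALSE)
  }
  pp <- pack_params(params)
  fs <- protocol$fs
  sample_ms <- 1000 / fs
  n <- round(protocol$duration * fs)
  t_ms <- (seq_len(n) - 1L) * sample_ms
  on_ms <- protocol$t_on * 1000
  off_ms <- protocol$t_off * 1000
  seg <- findInterval(t_ms, c(on_ms, off_ms)) # 0 pre, 1 step, 2 post
  hold_state <- hh_steady_state(protocol$holding, pp)

  traces <- with_seed(seed, lapply(protocol$steps, function(v_cmd) {
    i <- numeric(n)
    pre <- vclamp_segment(params, pp, hold_state, protocol$holding,
                          t_ms[seg == 0], on_ms)
    i[seg == 0] <- pre$i
    stp <- vclamp_segment(params, pp, pre$state, v_cmd,
                          t_ms[seg == 1] - on_ms, off_ms - on_ms)
    i[seg == 1] <- stp$i
    post <- vclamp_segment(params, pp, stp$state, protocol$holding,
                           t_ms[seg == 2] - off_ms,
                           protocol$duration * 1000 - off_ms)
    i[seg == 2] <- post$i
    if (include_transient) {
      dv <- v_cmd - protocol$holding
      i <- i + cap_transient(t_ms, sample_ms, params$c_m, params$r_s, dv, on_ms)
      i <- i + cap_transient(t_ms, sample_ms, params$c_m, params$r_s, -dv, off_ms)
    }
    if (params$noise_sd > 0) i <- i + stats::rnorm(n, 0, params$noise_sd)
    trace(i, fs = fs, kind = "current")
  }))
  sweep_set(protocol, traces, cell_id = cell_id, genotype = genotype,
            week = week)
}

#' Describe spontaneous synaptic input statistics
#'
#' Parameters of the (optionally burst-modulated) doubly stochastic
#' Poisson process that drives [simulate_synaptic_recording()].
#' Background events arrive at `rate_hz`; burst epochs arrive at
#' `burst_rate_hz`, last `burst_duration_s` on average (gamma-distributed,
#' shape 4), and carry events at `burst_event_rate_hz` while they last.
#'
#' @param rate_hz Background event rate, Hz.
#' @param amp_mean_pA Mean event amplitude (inward, reported positive), pA.
#' @param amp_cv Coefficient of variation of the log-normal amplitudes.
#' @param tau_rise_ms,tau_decay_ms Biexponential kernel time constants, ms
#'   (`tau_rise_ms < tau_decay_ms`).
#' @param burst_rate_hz Burst-epoch rate, Hz (0 for a plain Poisson train).
#' @param burst_event_rate_hz Within-burst event rate, Hz.
#' @param burst_duration_s Mean burst-epoch duration, s.
#'
#' @return An object of class `ck_synaptic_stats`.
#' @export
synaptic_stats <- function(rate_hz = 0.5, amp_mean_pA = 20, amp_cv = 0.3,
                           tau_rise_ms = 2, tau_decay_ms = 10,
                           burst_rate_hz = 0, burst_event_rate_hz = 0,
                           burst_duration_s = 0.3) {
  if (any(c(rate_hz, burst_rate_hz, burst_event_rate_hz) < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  if (tau_rise_ms >= tau_decay_ms) {
    stop("tau_rise_ms must be < tau_decay_ms", call. = FALSE)
  }
  structure(list(rate_hz = rate_hz, amp_mean_pA = amp_mean_pA,
                 amp_cv = amp_cv, tau_rise_ms = tau_rise_ms,
                 tau_decay_ms = tau_decay_ms, burst_rate_hz = burst_rate_hz,
                 burst_event_rate_hz = burst_event_rate_hz,
                 burst_duration_s = burst_duration_s),
            class = "ck_synaptic_stats")
}

#' Simulate a gap-free synaptic-current recording
#'
#' Builds a voltage-clamp current trace of spontaneous excitatory
#' postsynaptic currents: baseline plus Gaussian noise plus a sum of
#' inward biexponential kernels \eqn{A (e^{-t/\tau_d} - e^{-t/\tau_r})}
#' peak-normalized to amplitude \eqn{-A}. Event times come from the
#' doubly stochastic process in [synaptic_stats()]; amplitudes are
#' log-normal. The ground-truth event table and burst-epoch table are
#' returned alongside the trace.
#'
#' @param event_stats A [synaptic_stats()] object.
#' @param duration_s Recording length, s.
#' @param fs Sampling rate, Hz; must resolve the rise time
#'   (`fs * tau_rise >= 5`).
#' @param noise_sd Baseline current-noise SD, pA.
#' @param seed Integer seed.
#' @param baseline_pA Holding-current baseline, pA.
#'
#' @return A list of class `ck_synth_recording` with elements `trace`
#'   (a current [trace()]), `events` (tibble: `time_s`, `amplitude_pA`,
#'   `source`, `burst_id`) and `epochs` (tibble: `start_s`, `end_s`).
#' @export
simulate_synaptic_recording <- function(event_stats, duration_s, fs = 5000,
                                        noise_sd = 2, seed = 1,
                                        baseline_pA = 0) {
  stopifnot(inherits(event_stats, "ck_synaptic_stats"))
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  es <- event_stats
  if (fs * es$tau_rise_ms / 1000 < 5) {
    stop("fs too low to resolve tau_rise (need fs * tau_rise >= 5)",
         call. = FALSE)
  }
  n <- round(duration_s * fs)
  out <- with_seed(seed, {
    n_bg <- stats::rpois(1, es$rate_hz * duration_s)
    bg_t <- sort(stats::runif(n_bg, 0, duration_s))
    n_ep <- stats::rpois(1, es$burst_rate_hz * duration_s)
    ep_start <- sort(stats::runif(n_ep, 0, duration_s))
    ep_dur <- if (n_ep > 0) {
      stats::rgamma(n_ep, shape = 4, scale = es$burst_duration_s / 4)
    } else numeric(0)
    ep_end <- pmin(ep_start + ep_dur, duration_s)
    ev <- tibble::tibble(time_s = bg_t,
                         source = rep("background", n_bg),
                         burst_id = rep(NA_integer_, n_bg))
    if (n_ep > 0) {
      for (k in seq_len(n_ep)) {
        dk <- ep_end[k] - ep_start[k]
        nk <- stats::rpois(1, es$burst_event_rate_hz * dk)
        if (nk > 0) {
          ev <- dplyr::bind_rows(ev, tibble::tibble(
            time_s = ep_start[k] + sort(stats::runif(nk, 0, dk)),
            source = "burst", burst_id = k))
        }
      }
    }
    ev <- dplyr::arrange(ev, .data$time_s)
    n_ev <- nrow(ev)
    sdlog <- sqrt(log(1 + es$amp_cv^2))
    meanlog <- log(es$amp_mean_pA) - sdlog^2 / 2
    ev$amplitude_pA <- if (n_ev > 0) stats::rlnorm(n_ev, meanlog, sdlog) else numeric(0)
    x <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
    x <- x + baseline_pA
    if (n_ev > 0) {
      tr_ms <- es$tau_rise_ms
      td_ms <- es$tau_decay_ms
      t_peak <- tr_ms * td_ms / (td_ms - tr_ms) * log(td_ms / tr_ms)
      gmax <- exp(-t_peak / td_ms) - exp(-t_peak / tr_ms)
      kern_len <- ceiling(8 * td_ms / 1000 * fs)
      for (j in seq_len(n_ev)) {
        i0 <- floor(ev$time_s[j] * fs) + 1L
        idx <- i0:min(i0 + kern_len, n)
        if (idx[1] > n) next
        s_ms <- ((idx - 1) / fs - ev$time_s[j]) * 1000
        s_ms[s_ms < 0] <- 0
        x[idx] <- x[idx] - ev$amplitude_pA[j] *
          (exp(-s_ms / td_ms) - exp(-s_ms / tr_ms)) / gmax
      }
    }
    list(x = x,
         events = ev[, c("time_s", "amplitude_pA", "source", "burst_id")],
         epochs = tibble::tibble(start_s = ep_start, end_s = ep_end))
  })
  structure(
    list(trace = trace(out$x, fs = fs, kind = "current"),
         events = out$events, epochs = out$epochs),
    class = "ck_synth_recording"
  )
}

#' @export
print.ck_synth_recording <- function(x, ...) {
  cat(sprintf("<ck_synth_recording> %.0f s @ %g kHz, %d true events, %d burst epochs\n",
              trace_duration(x$trace), x$trace$fs / 1000,
              nrow(x$events), nrow(x$epochs)))
  invisible(x)
}
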