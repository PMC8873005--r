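#' Biophysical parameters of a model neuron
#'
#' Single-compartment conductance model with transient sodium, delayed
#' rectifier potassium, fast inactivating (A-type, KCNA5-like) potassium,
#' slow M-type (spike-frequency adaptation) potassium and leak
#' conductances:
#' \deqn{C_m dV/dt = -g_{Na} m^3 h (V-E_{Na}) - g_{Kd} n^4 (V-E_K)
#'       - g_A a b (V-E_K) - g_M p (V-E_K) - g_L (V-E_L) + I_{inj}(t) + \xi(t)}
#' Sodium and delayed-rectifier gating uses Traub-Miles style rate
#' functions with a single voltage shift `v_t` that places the spike
#' threshold; the A-type conductance uses Boltzmann steady states with
#' fixed time constants (fast activation, slower inactivation), which is
#' what lets it carve out a fast afterhyperpolarization and narrow the
#' spike.
#'
#' @param c_m Membrane capacitance, pF.
#' @param g_na Peak sodium conductance, nS.
#' @param g_kd Delayed-rectifier potassium conductance, nS.
#' @param g_a A-type (fast) potassium conductance, nS.
#' @param g_l Leak conductance, nS.
#' @param e_na,e_k,e_l Reversal potentials, mV (`e_k < e_l < 0 < e_na`).
#' @param r_s Series resistance, MOhm (voltage clamp only).
#' @param noise_sd Additive current-noise SD, pA.
#' @param v_t Voltage shift of the Na/Kd rate functions, mV. More
#'   depolarized values raise the spike threshold.
#' @param a_vhalf,a_k A-type activation Boltzmann midpoint (mV) and slope.
#' @param a_tau A-type activation time constant, ms.
#' @param b_vhalf,b_k A-type inactivation Boltzmann midpoint and slope.
#' @param b_tau A-type inactivation time constant, ms.
#' @param g_m Slow M-type potassium (spike-frequency adaptation)
#'   conductance, nS.
#' @param p_tau_max Peak time constant of the M-type gate, ms.
#' @param p_vhalf Activation midpoint of the M-type gate, mV; placed near
#'   spike voltages so the gate accumulates during firing (adaptation)
#'   rather than at rest.
#'
#' @return An object of class `ck_neuron_params` (named list).
#' @export
#' @examples
#' p <- neuron_params(g_na = 0, g_kd = 0, g_a = 0) # passive cell
neuron_params <- function(c_m = 30, g_na = 80, g_kd = 20, g_a = 5,
                          g_l = 1, e_na = 60, e_k = -90, e_l = -65,
                          r_s = 10, noise_sd = 0, v_t = -50,
                          a_vhalf = -30, a_k = 10, a_tau = 1,
                          b_vhalf = -60, b_k = 6, b_tau = 20,
                          g_m = 2, p_tau_max = 300, p_vhalf = -20) {
  p <- list(c_m = c_m, g_na = g_na, g_kd = g_kd, g_a = g_a, g_l = g_l,
            e_na = e_na, e_k = e_k, e_l = e_l, r_s = r_s,
            noise_sd = noise_sd, v_t = v_t,
            a_vhalf = a_vhalf, a_k = a_k, a_tau = a_tau,
            b_vhalf = b_vhalf, b_k = b_k, b_tau = b_tau,
            g_m = g_m, p_tau_max = p_tau_max, p_vhalf = p_vhalf)
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("all parameters must be finite", call. = FALSE)
  if (any(c(g_na, g_kd, g_a, g_l, g_m) < 0)) {
    stop("conductances must be >= 0", call. = FALSE)
  }
  if (c_m <= 0) stop("c_m must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!(e_k < e_l && e_l < 0 && 0 < e_na)) {
    stop("need e_k < e_l < 0 < e_na", call. = FALSE)
  }
  structure(p, class = "ck_neuron_params")
}

#' @export
print.ck_neuron_params <- function(x, ...) {
  cat(sprintf(
    "<ck_neuron_params> C=%g pF, gNa=%g gKd=%g gA=%g gL=%g nS, noise %g pA\n",
    x$c_m, x$g_na, x$g_kd, x$g_a, x$g_l, x$noise_sd))
  invisible(x)
}

pack_params <- function(p) {
  c(p$c_m, p$g_na, p$g_kd, p$g_a, p$g_l, p$e_na, p$e_k, p$e_l, p$v_t,
    p$a_vhalf, p$a_k, p$a_tau, p$b_vhalf, p$b_k, p$b_tau, p$g_m,
    p$p_tau_max, p$p_vhalf)
}
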