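#' Gating-variable kinetics
#'
#' A `gating_kinetics` object describes one Boltzmann steady-state curve and
#' one sigmoidal voltage-dependent time constant,
#' \deqn{x_\infty(V) = \frac{1}{1 + \exp((V - V_h)/k)}, \qquad
#'       \tau_x(V) = \tau_0 + \frac{\tau_A}{1 + \exp((V - V_{h,\tau})/k_\tau)},}
#' the form used for every activation/inactivation variable of the PD neuron
#' model.  `slope` and `tau_slope` are signed: a negative `slope` gives a
#' curve that increases with depolarization (activation), a positive one a
#' curve that decreases (inactivation, or the hyperpolarization-activated
#' current's activation).  `tau_amplitude` may be negative (the CaS and KCa
#' time constants decrease sigmoidally with depolarization).
#'
#' @param half_voltage midpoint of the steady-state curve (mV).
#' @param slope signed slope factor of the steady-state curve (mV).
#' @param tau_base baseline of the time constant (ms).
#' @param tau_amplitude sigmoidal amplitude of the time constant (ms, signed).
#' @param tau_half_voltage midpoint of the time-constant sigmoid (mV).
#' @param tau_slope signed slope factor of the time-constant sigmoid (mV).
#' @return An object of class `gating_kinetics`.
#' @examples
#' # h-current activation used by the control PD model
#' gk <- gating_kinetics(-70, 6, 50, 200, -42.2, -8.73)
#' gate_inf(gk, -70)   # 0.5 at the midpoint
#' gate_tau(gk, -42.2) # tau_base + tau_amplitude/2 at the tau midpoint
#' @export
gating_kinetics <- function(half_voltage, slope, tau_base, tau_amplitude,
                            tau_half_voltage, tau_slope) {
  stopifnot(is.finite(half_voltage), is.finite(slope), slope != 0,
            is.finite(tau_base), is.finite(tau_amplitude),
            is.finite(tau_half_voltage), is.finite(tau_slope), tau_slope != 0)
  structure(list(half_voltage = half_voltage, slope = slope,
                 tau_base = tau_base, tau_amplitude = tau_amplitude,
                 tau_half_voltage = tau_half_voltage, tau_slope = tau_slope),
            class = "gating_kinetics")
}

#' @rdname gating_kinetics
#' @param kin a `gating_kinetics` object.
#' @param V membrane potential (mV), vectorized.
#' @export
gate_inf <- function(kin, V) {
  1 / (1 + exp((V - kin$half_voltage) / kin$slope))
}

#' Slope of the steady-state curve, dx_inf/dV (1/mV)
#' @rdname gating_kinetics
#' @export
gate_inf_slope <- function(kin, V) {
  x <- gate_inf(kin, V)
  -x * (1 - x) / kin$slope
}

#' @rdname gating_kinetics
#' @export
gate_tau <- function(kin, V) {
  kin$tau_base + kin$tau_amplitude /
    (1 + exp((V - kin$tau_half_voltage) / kin$tau_slope))
}
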