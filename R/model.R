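#' Ionic channel specification
#'
#' One voltage- (and, for KCa, calcium-) gated channel of the PD neuron model.
#' The channel current is \eqn{I = \bar g\, m^r h^q (V - E)} with ionic
#' currents positive-outward.  Only CaT carries an inactivation gate
#' (\eqn{q = 1}); the calcium-coupled flag is set only for KCa, whose
#' steady-state activation is the product of a saturating calcium factor
#' \eqn{[Ca]/([Ca]+K_d)} and a Boltzmann voltage factor.
#'
#' @param name channel identifier (`"h"`, `"CaT"`, `"CaS"`, `"KCa"`).
#' @param gbar maximal conductance (µS), non-negative.
#' @param reversal reversal potential (mV).  For CaT/CaS this is the shared
#'   constant calcium reversal; see [pd_control_params()].
#' @param r integer activation exponent (1, 3 or 4).
#' @param activation `gating_kinetics` for the activation variable.
#' @param inactivation `gating_kinetics` for the inactivation variable, or
#'   `NULL` (then \eqn{q = 0}).
#' @param calcium_coupled logical; `TRUE` only for KCa.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, gbar, reversal, r, activation,
                         inactivation = NULL, calcium_coupled = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(gbar), gbar >= 0, is.finite(reversal),
            r %in% c(1L, 3L, 4L),
            inherits(activation, "gating_kinetics"),
            is.null(inactivation) || inherits(inactivation, "gating_kinetics"),
            is.logical(calcium_coupled))
  structure(list(name = name, gbar = gbar, reversal = reversal,
                 r = as.integer(r), q = if (is.null(inactivation)) 0L else 1L,
                 activation = activation, inactivation = inactivation,
                 calcium_coupled = isTRUE(calcium_coupled)),
            class = "channel_spec")
}

#' Control parameters of the PD neuron model
#'
#' Builds the full parameter set of the conductance-based PD model: four
#' active channels (h, CaT, CaS, KCa), leak, membrane capacitance and the
#' first-order intracellular calcium buffering
#' \deqn{\tau_{Ca}\frac{d[Ca]}{dt} = -F\,(I_{CaT}+I_{CaS}) - [Ca] + C_0.}
#'
#' Units are absolute per-cell units throughout: mV, ms, nA, µS, nF, µM.
#'
#' The calcium reversal potential is a single constant `E_Ca` (the model does
#' not update it with `[Ca]`); its default is calibrated so that the
#' linearized CaT/CaS activation-branch resistances match the published
#' component table (see the methods vignette).  The leak reversal `E_leak` is
#' computed at construction so that `V_rest` is an equilibrium of the full
#' model under zero input current; pass `E_leak` explicitly to override.
#'
#' @param g_h,g_CaT,g_CaS,g_KCa,g_leak maximal conductances (µS).
#' @param E_h,E_K reversal potentials (mV) of the h and KCa currents.
#' @param E_Ca constant calcium reversal potential (mV), positive.
#' @param C membrane capacitance (nF).
#' @param tau_Ca calcium buffering time constant (ms).
#' @param C0 background intracellular calcium concentration (µM).
#' @param F_Ca current-to-concentration factor (µM/nA).
#' @param Kd half-saturation constant of the KCa calcium factor (µM).
#' @param V_rest control resting potential (mV) used to compute `E_leak`.
#' @param E_leak leak reversal potential (mV), or `NULL` to compute it from
#'   `V_rest` (zero-current rest).
#' @param h_half,h_slope midpoint and signed slope of the h-current
#'   activation curve (mV).
#' @return An object of class `pd_params`: list with elements `channels`
#'   (named list of `channel_spec`), `C`, `g_leak`, `E_leak`, `E_Ca`,
#'   `calcium` (list `F`, `tau_Ca`, `C0`, `Kd`) and `V_rest`.
#' @examples
#' p <- pd_control_params()
#' names(p$channels)
#' p$E_leak  # computed so that -55 mV is the zero-input rest
#' @export
pd_control_params <- function(g_h = 0.219, g_CaT = 2.25, g_CaS = 5.4,
                              g_KCa = 150, g_leak = 0.105,
                              E_h = -20, E_K = -80, E_Ca = 54,
                              C = 12, tau_Ca = 300, C0 = 0.5, F_Ca = 0.515,
                              Kd = 30, V_rest = -55, E_leak = NULL,
                              h_half = -70, h_slope = 6) {
  stopifnot(C > 0, tau_Ca > 0, C0 > 0, F_Ca > 0, Kd > 0, E_Ca > 0)
  ch <- list(
    h = channel_spec("h", g_h, E_h, 1L,
      activation = gating_kinetics(h_half, h_slope, 50, 200, -42.2, -8.73)),
    CaT = channel_spec("CaT", g_CaT, E_Ca, 3L,
      activation = gating_kinetics(-25, -7.2, 1, 9, -58, 17),
      inactivation = gating_kinetics(-36, 7, 80, 10, -50, 17)),
    CaS = channel_spec("CaS", g_CaS, E_Ca, 3L,
      activation = gating_kinetics(-22, -8.5, 16, -13.1, -25.1, -16.4)),
    KCa = channel_spec("KCa", g_KCa, E_K, 4L,
      activation = gating_kinetics(-51, -8, 90.3, -75.1, -46, -22.7),
      calcium_coupled = TRUE)
  )
  p <- structure(list(channels = ch, C = C, g_leak = g_leak, E_leak = NA_real_,
                      E_Ca = E_Ca,
                      calcium = list(F = F_Ca, tau_Ca = tau_Ca, C0 = C0, Kd = Kd),
                      V_rest = V_rest),
                 class = "pd_params")
  p$E_leak <- if (is.null(E_leak)) leak_reversal(p, V_rest) else E_leak
  p
}

#' Leak reversal potential making `V_star` a zero-input equilibrium
#'
#' Solves \eqn{0 = -g_{leak}(V^* - E_{leak}) - \sum_i I_i^*} for `E_leak`,
#' with all active currents at their steady states for `V_star`.
#'
#' @param params a `pd_params` object (its `E_leak` is ignored).
#' @param V_star target resting potential (mV).
#' @return `E_leak` (mV).
#' @export
leak_reversal <- function(params, V_star) {
  I_act <- total_active_current(params, V_star)
  V_star + I_act / params$g_leak
}

#' Steady-state gating values of a channel
#'
#' Returns the steady-state activation (and inactivation, if the channel has
#' one) at potential `V`.  For the calcium-coupled KCa channel the activation
#' steady state is the product
#' \eqn{m_\infty = \frac{[Ca]}{[Ca]+K_d}\cdot\frac{1}{1+\exp(-(V+51)/8)}}.
#'
#' @param channel a `channel_spec`.
#' @param V membrane potential (mV).
#' @param Ca intracellular calcium concentration (µM); used only when the
#'   channel is calcium-coupled.  Negative values are an error.
#' @param Kd half-saturation constant (µM) of the calcium factor.
#' @return list with `m_inf` and (if present) `h_inf`, each in \[0, 1\].
#' @export
eval_steady_state <- function(channel, V, Ca = 0, Kd = 30) {
  stopifnot(is.finite(V))
  if (channel$calcium_coupled && any(Ca < 0))
    stop("negative calcium concentration")
  m <- gate_inf(channel$activation, V)
  if (channel$calcium_coupled) m <- m * Ca / (Ca + Kd)
  out <- list(m_inf = m)
  if (!is.null(channel$inactivation))
    out$h_inf <- gate_inf(channel$inactivation, V)
  out
}

#' Voltage-dependent time constants of a channel
#'
#' @inheritParams eval_steady_state
#' @return list with `tau_m` and (if present) `tau_h`, in ms, strictly
#'   positive over the subthreshold range.
#' @export
eval_time_constants <- function(channel, V) {
  stopifnot(is.finite(V))
  out <- list(tau_m = gate_tau(channel$activation, V))
  if (!is.null(channel$inactivation))
    out$tau_h <- gate_tau(channel$inactivation, V)
  out
}

#' Instantaneous channel current
#'
#' \eqn{I = \bar g\, m^r h^q (V - E)}, positive-outward.
#'
#' @param channel a `channel_spec`.
#' @param V membrane potential (mV).
#' @param m activation variable in \[0, 1\].
#' @param h inactivation variable in \[0, 1\] (ignored when \eqn{q = 0}).
#' @return current (nA).
#' @export
channel_current <- function(channel, V, m, h = 1) {
  channel$gbar * m^channel$r * (if (channel$q == 1L) h else 1) *
    (V - channel$reversal)
}

## total steady-state active (non-leak) current at clamped V (nA)
total_active_current <- function(params, V) {
  Ca <- calcium_steady_state(params, V)
  s <- 0
  for (ch in params$channels) {
    ss <- eval_steady_state(ch, V, Ca, params$calcium$Kd)
    s <- s + channel_current(ch, V, ss$m_inf,
                             if (is.null(ss$h_inf)) 1 else ss$h_inf)
  }
  s
}

#' Steady-state intracellular calcium at clamped potential
#'
#' The fixed point of the calcium buffering equation,
#' \eqn{[Ca]^* = C_0 - F\,(I_{CaT}^* + I_{CaS}^*)}, with the calcium currents
#' at their gating steady states for `V`.  Because the calcium currents are
#' inward (negative) at subthreshold potentials, \eqn{[Ca]^* \ge C_0}.
#'
#' @param params a `pd_params` object.
#' @param V clamped membrane potential (mV).
#' @return steady-state calcium concentration (µM).
#' @export
calcium_steady_state <- function(params, V) {
  ICa <- 0
  for (nm in c("CaT", "CaS")) {
    ch <- params$channels[[nm]]
    ss <- eval_steady_state(ch, V)
    ICa <- ICa + channel_current(ch, V, ss$m_inf,
                                 if (is.null(ss$h_inf)) 1 else ss$h_inf)
  }
  params$calcium$C0 - params$calcium$F * ICa
}

#' Model state
#'
#' @param V membrane potential (mV).
#' @param m_h,m_CaT,h_CaT,m_CaS,m_KCa gating variables in \[0, 1\].
#' @param Ca intracellular calcium (µM), non-negative.
#' @return named numeric vector of length 7 (class `pd_state`).
#' @export
pd_state <- function(V, m_h, m_CaT, h_CaT, m_CaS, m_KCa, Ca) {
  g <- c(m_h = m_h, m_CaT = m_CaT, h_CaT = h_CaT, m_CaS = m_CaS, m_KCa = m_KCa)
  stopifnot(all(g >= 0 & g <= 1), Ca >= 0, is.finite(V))
  structure(c(V = V, g, Ca = Ca), class = "pd_state")
}

#' Right-hand side of the PD model
#'
#' The full nonlinear vector field: current conservation for `V`, first-order
#' relaxation of every gating variable to its (voltage- and, for KCa,
#' calcium-dependent) steady state, and calcium buffering.  This is the plain
#' R reference implementation; the integrator uses an equivalent compiled
#' core that is tested against it.
#'
#' @param state a `pd_state` (or named numeric with the same elements).
#' @param I_inp input current (nA), positive inward/depolarizing.
#' @param params a `pd_params` object.
#' @return named numeric vector of derivatives (per ms).
#' @export
model_rhs <- function(state, I_inp, params) {
  V <- state[["V"]]; Ca <- state[["Ca"]]
  ch <- params$channels; kd <- params$calcium$Kd
  I_h   <- channel_current(ch$h,   V, state[["m_h"]])
  I_CaT <- channel_current(ch$CaT, V, state[["m_CaT"]], state[["h_CaT"]])
  I_CaS <- channel_current(ch$CaS, V, state[["m_CaS"]])
  I_KCa <- channel_current(ch$KCa, V, state[["m_KCa"]])
  I_leak <- params$g_leak * (V - params$E_leak)
  dV <- (-I_leak - I_h - I_CaT - I_CaS - I_KCa + I_inp) / params$C

  d_gate <- function(channel, x, gate = "activation") {
    kin <- channel[[gate]]
    xi <- gate_inf(kin, V)
    if (gate == "activation" && channel$calcium_coupled)
      xi <- xi * Ca / (Ca + kd)
    (xi - x) / gate_tau(kin, V)
  }
  dCa <- (-params$calcium$F * (I_CaT + I_CaS) - Ca + params$calcium$C0) /
    params$calcium$tau_Ca
  c(V = dV,
    m_h   = d_gate(ch$h,   state[["m_h"]]),
    m_CaT = d_gate(ch$CaT, state[["m_CaT"]]),
    h_CaT = d_gate(ch$CaT, state[["h_CaT"]], "inactivation"),
    m_CaS = d_gate(ch$CaS, state[["m_CaS"]]),
    m_KCa = d_gate(ch$KCa, state[["m_KCa"]]),
    Ca = dCa)
}

#' @export
print.pd_params <- function(x, ...) {
  cat("PD neuron model parameters (mV, ms, nA, µS, nF, µM)\n")
  cat(sprintf("  C = %g nF, g_leak = %g µS, E_leak = %.3f mV, E_Ca = %g mV\n",
              x$C, x$g_leak, x$E_leak, x$E_Ca))
  for (ch in x$channels)
    cat(sprintf("  %-4s gbar = %7.3f µS  E = %6.1f mV  m^%d%s%s\n",
                ch$name, ch$gbar, ch$reversal, ch$r,
                if (ch$q == 1L) " h" else "",
                if (ch$calcium_coupled) "  [Ca-coupled]" else ""))
  cat(sprintf("  calcium: tau_Ca = %g ms, C0 = %g µM, F = %g µM/nA, Kd = %g µM\n",
              x$calcium$tau_Ca, x$calcium$C0, x$calcium$F, x$calcium$Kd))
  invisible(x)
}
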