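## pack a pd_params into the flat parameter vector the compiled core expects
pack_params <- function(params) {
  ch <- params$channels
  kin <- function(k) c(k$half_voltage, k$slope, k$tau_base, k$tau_amplitude,
                       k$tau_half_voltage, k$tau_slope)
  c(params$C, params$g_leak, params$E_leak,
    ch$h$gbar, ch$h$reversal, ch$CaT$gbar, ch$CaS$gbar, params$E_Ca,
    ch$KCa$gbar, ch$KCa$reversal,
    params$calcium$F, params$calcium$tau_Ca, params$calcium$C0,
    params$calcium$Kd,
    kin(ch$h$activation), kin(ch$CaT$activation), kin(ch$CaT$inactivation),
    kin(ch$CaS$activation), kin(ch$KCa$activation))
}

#' Integrate the PD model with fixed-step RK4
#'
#' Classical fourth-order Runge-Kutta on the stimulus grid (step = stimulus
#' `dt`), with the stimulus interpolated linearly at half-steps.  The core is
#' compiled; an equivalent plain-R right-hand side ([model_rhs()]) is
#' exported and the two are held in agreement by the test suite.
#'
#' @param params a `pd_params` object.
#' @param stimulus a `pd_stimulus` (uniform grid; columns `t` ms, `I` nA).
#' @param init initial state: a `pd_state`/named numeric of length 7, or an
#'   `equilibrium_state` from [find_equilibrium()] (its holding current is
#'   *not* added automatically; superimpose it on the stimulus).
#' @return A `pd_trace`: data.frame with columns `t`, `V`, `m_h`, `m_CaT`,
#'   `h_CaT`, `m_CaS`, `m_KCa`, `Ca`, `I_inp`.
#' @export
integrate_pd <- function(params, stimulus, init) {
  if (inherits(init, "equilibrium_state")) init <- init$state
  stopifnot(length(init) == 7L)
  dt <- diff(stimulus$t[1:2])
  if (max(abs(diff(stimulus$t) - dt)) > 1e-9 * dt)
    stop("stimulus grid is not uniform")
  y <- rk4_pd_cpp(as.numeric(init), stimulus$I, dt, pack_params(params))
  colnames(y) <- c("V", "m_h", "m_CaT", "h_CaT", "m_CaS", "m_KCa", "Ca")
  out <- data.frame(t = stimulus$t, y, I_inp = stimulus$I)
  class(out) <- c("pd_trace", "data.frame")
  attr(out, "dt") <- dt
  out
}

#' Equilibrium of the PD model at a chosen holding potential
#'
#' Because the calcium reversal is constant, the equilibrium at a clamped
#' potential is closed-form: gating variables at their steady states for
#' `V_star` (KCa at the steady-state calcium), calcium at its fixed point,
#' and the holding current equal to the total steady ionic plus leak current
#' at `V_star`.  The returned state is a fixed point of [model_rhs()] under
#' constant input `I_hold`.
#'
#' @param params a `pd_params` object.
#' @param V_star holding potential (mV), subthreshold.
#' @return An `equilibrium_state`: list with `V_star`, `state` (a
#'   `pd_state`), `Ca_star`, `I_hold` (nA).
#' @examples
#' eq <- find_equilibrium(pd_control_params(), -55)
#' max(abs(model_rhs(eq$state, eq$I_hold, pd_control_params())))  # ~ 0
#' @export
find_equilibrium <- function(params, V_star) {
  stopifnot(V_star >= -100, V_star <= -40)
  Ca <- calcium_steady_state(params, V_star)
  ch <- params$channels; kd <- params$calcium$Kd
  st <- pd_state(V_star,
                 m_h   = gate_inf(ch$h$activation, V_star),
                 m_CaT = gate_inf(ch$CaT$activation, V_star),
                 h_CaT = gate_inf(ch$CaT$inactivation, V_star),
                 m_CaS = gate_inf(ch$CaS$activation, V_star),
                 m_KCa = gate_inf(ch$KCa$activation, V_star) * Ca / (Ca + kd),
                 Ca = Ca)
  I_hold <- total_active_current(params, V_star) +
    params$g_leak * (V_star - params$E_leak)
  structure(list(V_star = V_star, state = st, Ca_star = Ca, I_hold = I_hold),
            class = "equilibrium_state")
}

#' Run the chirp protocol on the nonlinear model at a holding potential
#'
#' Equilibrates at `V_star` (computed holding current), superimposes the
#' chirp on the holding current and integrates.  Starting exactly at the
#' equilibrium avoids an onset transient, so the full record is usable for
#' the FFT.
#'
#' @param params a `pd_params` object.
#' @param V_star holding potential (mV).
#' @param chirp a chirp stimulus from [chirp_current()].
#' @return a `pd_trace`; attribute `"equilibrium"` carries the equilibrium.
#' @export
run_chirp_nonlinear <- function(params, V_star,
                                chirp = chirp_current(0.5, 0, 5, 10)) {
  eq <- find_equilibrium(params, V_star)
  tr <- integrate_pd(params, offset_stimulus(chirp, eq$I_hold), eq)
  attr(tr, "equilibrium") <- eq
  tr
}

#' Write a trace as CSV
#' @param trace a `pd_trace`.
#' @param path output file.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("PD equilibrium at V* = %g mV: Ca* = %.4f µM, I_hold = %.4f nA\n",
              x$V_star, x$Ca_star, x$I_hold))
  print(round(unclass(x$state), 6))
  invisible(x)
}
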