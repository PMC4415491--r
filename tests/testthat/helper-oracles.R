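# Independent oracles used across the test files.  These deliberately avoid
# the package's own code paths wherever they stand in judgement of them.

# one classical RK4 step built on the plain-R right-hand side; judges the
# compiled integrator core
rk4_step_r <- function(state, I0, I1, dt, params) {
  k1 <- model_rhs(state, I0, params)
  Im <- (I0 + I1) / 2
  k2 <- model_rhs(state + dt / 2 * k1, Im, params)
  k3 <- model_rhs(state + dt / 2 * k2, Im, params)
  k4 <- model_rhs(state + dt * k3, I1, params)
  unclass(state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
}

# total small-signal admittance of the model evaluated directly as a rational
# function of p (no partial fractions); judges the assembled circuit
direct_admittance <- function(params, eq, pval, dca_scale = 1) {
  V <- eq$V_star; st <- eq$state; ca <- params$calcium
  lin1 <- function(ch, m, h = 1) {
    g <- ch$gbar; E <- ch$reversal; r <- ch$r; q <- ch$q
    tm <- gate_tau(ch$activation, V)
    am <- g * r * m^(r - 1) * (if (q == 1) h else 1) * (V - E) *
      gate_inf_slope(ch$activation, V) / tm
    Y <- g * m^r * (if (q == 1) h else 1) + am / (pval + 1 / tm)
    if (q == 1) {
      th <- gate_tau(ch$inactivation, V)
      ah <- g * m^r * (V - E) * gate_inf_slope(ch$inactivation, V) / th
      Y <- Y + ah / (pval + 1 / th)
    }
    Y
  }
  YT <- if (params$channels$CaT$gbar > 0)
    lin1(params$channels$CaT, st[["m_CaT"]], st[["h_CaT"]]) else 0
  YS <- if (params$channels$CaS$gbar > 0)
    lin1(params$channels$CaS, st[["m_CaS"]]) else 0
  YH <- if (params$channels$h$gbar > 0)
    lin1(params$channels$h, st[["m_h"]]) else 0
  chK <- params$channels$KCa
  YK <- 0
  if (chK$gbar > 0) {
    mK <- st[["m_KCa"]]; tauK <- gate_tau(chK$activation, V)
    s_v <- gate_inf(chK$activation, V)
    dmdV <- (eq$Ca_star / (eq$Ca_star + ca$Kd)) *
      gate_inf_slope(chK$activation, V)
    dmdCa <- s_v * ca$Kd / (eq$Ca_star + ca$Kd)^2
    k1 <- chK$gbar * 4 * mK^3 * (V - chK$reversal) / tauK
    dCa_dV <- -(dca_scale * ca$F / ca$tau_Ca) * (YT + YS) /
      (pval + 1 / ca$tau_Ca)
    YK <- chK$gbar * mK^4 + k1 * (dmdV + dmdCa * dCa_dV) / (pval + 1 / tauK)
  }
  pval * params$C + params$g_leak + YT + YS + YH + YK
}

# total steady-state membrane current at clamped V (leak + active); judges
# the circuit's DC conductance by finite differences
steady_iv <- function(params, V) {
  I <- params$g_leak * (V - params$E_leak)
  Ca <- calcium_steady_state(params, V)
  for (ch in params$channels) {
    ss <- eval_steady_state(ch, V, Ca, params$calcium$Kd)
    I <- I + channel_current(ch, V, ss$m_inf,
                             if (is.null(ss$h_inf)) 1 else ss$h_inf)
  }
  I
}

control_chirp <- function(I_amp = 0.5) chirp_current(I_amp, 0, 5, 10)
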