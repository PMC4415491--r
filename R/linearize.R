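#' Series RL branch of the quasi-active circuit
#'
#' Each first-order admittance term \eqn{a/(p + b)} of the linearized channel
#' dynamics maps onto a series resistor-inductor branch with
#' \eqn{L = 1/a,\ R = b/a}, so that \eqn{1/(R + pL) = a/(p + b)}.
#' Internal units: R in MΩ, L in MΩ·ms (with conductances in µS and rate
#' `p` in 1/ms).  Signs may be negative (amplifying branches).
#'
#' @param label branch identifier (`m_CaT`, `h_CaT`, `m_CaS`, `m_h`,
#'   `KCa1`..`KCa5`).
#' @param R series resistance (MΩ, signed).
#' @param L series inductance (MΩ·ms, signed).
#' @param channel name of the source channel.
#' @return an `rl_branch` object.
#' @export
rl_branch <- function(label, R, L, channel = NA_character_) {
  stopifnot(is.finite(R), is.finite(L))
  structure(list(label = label, R = R, L = L, channel = channel),
            class = "rl_branch")
}

branch_from_term <- function(a, b, label, channel) {
  # admittance slope a (µS/ms), pole b (1/ms); zero-slope terms contribute
  # no branch (the channel's instantaneous conductance alone remains)
  if (abs(a) < 1e-300) return(NULL)
  rl_branch(label, R = b / a, L = 1 / a, channel = channel)
}

## slope of the KCa steady-state activation w.r.t. V and Ca at a point
kca_partials <- function(kin, V, Ca, Kd) {
  s <- gate_inf(kin, V)
  list(dV = (Ca / (Ca + Kd)) * gate_inf_slope(kin, V),
       dCa = s * Kd / (Ca + Kd)^2)
}

## first-order admittance slopes of a purely voltage-gated channel at eq
## returns list(g_inst, terms = list(list(a, b, gate)))
voltage_channel_terms <- function(channel, V, m, h = 1) {
  gbar <- channel$gbar; E <- channel$reversal
  r <- channel$r; q <- channel$q
  g_inst <- gbar * m^r * (if (q == 1L) h else 1)
  terms <- list()
  tau_m <- gate_tau(channel$activation, V)
  a_m <- gbar * r * m^(r - 1) * (if (q == 1L) h else 1) * (V - E) *
    gate_inf_slope(channel$activation, V) / tau_m
  terms$m <- list(a = a_m, b = 1 / tau_m)
  if (q == 1L) {
    tau_h <- gate_tau(channel$inactivation, V)
    a_h <- gbar * m^r * (V - E) *
      gate_inf_slope(channel$inactivation, V) / tau_h
    terms$h <- list(a = a_h, b = 1 / tau_h)
  }
  list(g_inst = g_inst, terms = terms)
}

#' Linearize one channel about an equilibrium
#'
#' Quasi-active (first-order perturbation) expansion of a channel current
#' about the holding equilibrium.  For the voltage-gated channels (h, CaT,
#' CaS) each gating variable yields one admittance term
#' \eqn{a/(p + 1/\tau_x^*)} with slope
#' \eqn{a = \bar g\,\partial_x(m^r h^q)\,(V^*-E)\,x_\infty'(V^*)/\tau_x^*},
#' plus the instantaneous conductance \eqn{\bar g\,m^{*r}h^{*q}}.
#'
#' For the calcium-coupled KCa channel the perturbation propagates along two
#' paths: directly through the voltage dependence of its activation, and
#' through the calcium concentration, which is itself driven by the
#' linearized CaT and CaS currents via the buffering equation
#' (\eqn{\delta[Ca] = -(F/\tau_{Ca})\,\delta(I_{CaT}+I_{CaS})/(p+1/\tau_{Ca})}).
#' The resulting admittance is a rational function with five simple poles
#' (\eqn{1/\tau_{mKCa}, 1/\tau_{Ca}, 1/\tau_{mCaS}, 1/\tau_{hCaT},
#' 1/\tau_{mCaT}}); partial-fraction expansion over those poles reduces it to
#' exactly five series RL branches, `KCa1`..`KCa5`.  The expansion residues
#' carry factors \eqn{1/(1/\tau_{Ca} - 1/\tau_{mKCa})} etc., which is why the
#' first branch (at the KCa activation pole) is negative at the control
#' resting potential while the other four are positive.
#'
#' The published component table derives the calcium perturbation from
#' calcium currents expressed in the mS-based unit convention of its
#' resistance columns — 1000 times the nA-based currents that drive the
#' simulated calcium pool (the giveaway is that the printed KCa2..KCa5
#' values equal the nA-based ones divided by exactly 1000, and KCa1's sign
#' flips only under that reading).  `dca_scale` reproduces that convention
#' by default; set `dca_scale = 1` for the strictly self-consistent
#' small-signal derivative of the simulated model.  The two differ only in
#' the (numerically small) KCa feedback branches; see the methods vignette.
#'
#' @param channel a `channel_spec` taken from `params$channels`.
#' @param eq an `equilibrium_state` from [find_equilibrium()].
#' @param params the `pd_params` the equilibrium was computed from (needed by
#'   the KCa expansion, which involves the calcium channels).
#' @param dca_scale scale applied to the calcium currents in the calcium
#'   perturbation path (1000 = publication convention, 1 = self-consistent).
#' @return list with `g_inst` (µS) and `branches` (list of `rl_branch`).
#' @export
linearize_channel <- function(channel, eq, params, dca_scale = 1000) {
  check_equilibrium_consistency(params, eq)
  V <- eq$V_star; st <- eq$state
  if (!channel$calcium_coupled) {
    nm <- channel$name
    m <- st[[paste0("m_", nm)]]
    h <- if (channel$q == 1L) st[[paste0("h_", nm)]] else 1
    vt <- voltage_channel_terms(channel, V, m, h)
    branches <- list()
    branches[[length(branches) + 1L]] <-
      branch_from_term(vt$terms$m$a, vt$terms$m$b, paste0("m_", nm), nm)
    if (channel$q == 1L)
      branches[[length(branches) + 1L]] <-
        branch_from_term(vt$terms$h$a, vt$terms$h$b, paste0("h_", nm), nm)
    return(list(g_inst = vt$g_inst,
                branches = Filter(Negate(is.null), branches)))
  }

  ## KCa: five-pole partial-fraction reduction
  ca <- params$calcium
  mK <- st[["m_KCa"]]
  tau_K <- gate_tau(channel$activation, V)
  dm <- kca_partials(channel$activation, V, eq$Ca_star, ca$Kd)
  # common factor of the activation-perturbation path (µS/ms per unit dm)
  k1 <- channel$gbar * 4 * mK^3 * (V - channel$reversal) / tau_K

  chT <- params$channels$CaT; chS <- params$channels$CaS
  vtT <- voltage_channel_terms(chT, V, st[["m_CaT"]], st[["h_CaT"]])
  vtS <- voltage_channel_terms(chS, V, st[["m_CaS"]])

  beta <- c(KCa1 = 1 / tau_K,                 # KCa activation pole
            KCa2 = 1 / ca$tau_Ca,             # calcium buffering pole
            KCa3 = vtS$terms$m$b,             # CaS activation pole
            KCa4 = vtT$terms$h$b,             # CaT inactivation pole
            KCa5 = vtT$terms$m$b)             # CaT activation pole
  if (min(dist(beta)) < 1e-9)
    stop("degenerate poles in KCa expansion; partial fractions undefined")

  cf <- -k1 * dm$dCa * dca_scale * ca$F / ca$tau_Ca  # calcium-path prefactor
  c2 <- cf * (vtT$g_inst + vtS$g_inst)        # two-pole (instantaneous Ca) term
  cj <- cf * c(KCa3 = vtS$terms$m$a, KCa4 = vtT$terms$h$a,
               KCa5 = vtT$terms$m$a)          # three-pole (gating) terms

  b1 <- beta[["KCa1"]]; b2 <- beta[["KCa2"]]
  A <- c(KCa1 = k1 * dm$dV + c2 / (b2 - b1) +
           sum(cj / ((b2 - b1) * (beta[3:5] - b1))),
         KCa2 = -c2 / (b2 - b1) + sum(cj / ((b1 - b2) * (beta[3:5] - b2))),
         KCa3 = 0, KCa4 = 0, KCa5 = 0)
  for (nm in names(cj))
    A[[nm]] <- cj[[nm]] / ((b1 - beta[[nm]]) * (b2 - beta[[nm]]))

  branches <- list()
  for (nm in names(beta)) {
    br <- branch_from_term(A[[nm]], beta[[nm]], nm, "KCa")
    if (!is.null(br)) branches[[length(branches) + 1L]] <- br
  }
  list(g_inst = channel$gbar * mK^4, branches = branches)
}

check_equilibrium_consistency <- function(params, eq) {
  ref <- find_equilibrium(params, eq$V_star)
  if (max(abs(unclass(ref$state) - unclass(eq$state))) > 1e-8 ||
      abs(ref$I_hold - eq$I_hold) > 1e-8 * max(1, abs(ref$I_hold)))
    stop("equilibrium state is inconsistent with the supplied parameters")
  invisible(TRUE)
}

#' Assemble the full equivalent RLC circuit at an equilibrium
#'
#' Parallel combination of the membrane capacitance, the leak conductance,
#' every channel's instantaneous conductance and every channel's RL
#' branches.  The full control model yields exactly nine branches
#' (`m_CaT`, `h_CaT`, `m_CaS`, `m_h`, `KCa1`..`KCa5`); knocking a channel out
#' (gbar = 0) removes its instantaneous term and its branches and nothing
#' else.
#'
#' @param params a `pd_params` object.
#' @param eq an `equilibrium_state` from [find_equilibrium()]; computed at
#'   `params$V_rest` when omitted.
#' @inheritParams linearize_channel
#' @return A `linear_circuit`: list with `C` (nF), `g_inst` (named numeric,
#'   µS: `leak`, `h`, `CaT`, `CaS`, `KCa` as present), `branches` (list of
#'   `rl_branch`), `V_star`.
#' @export
assemble_linear_circuit <- function(params,
                                    eq = find_equilibrium(params, params$V_rest),
                                    dca_scale = 1000) {
  g_inst <- c(leak = params$g_leak)
  branches <- list()
  for (nm in c("CaT", "CaS", "h", "KCa")) {
    ch <- params$channels[[nm]]
    if (ch$gbar <= 0) next
    lin <- linearize_channel(ch, eq, params, dca_scale = dca_scale)
    g_inst[[nm]] <- lin$g_inst
    branches <- c(branches, lin$branches)
  }
  ord <- c("m_CaT", "h_CaT", "m_CaS", "m_h", paste0("KCa", 1:5))
  labs <- vapply(branches, `[[`, "", "label")
  branches <- branches[order(match(labs, ord))]
  structure(list(C = params$C, g_inst = g_inst, branches = branches,
                 V_star = eq$V_star),
            class = "linear_circuit")
}

#' Closed-form impedance of a linear circuit
#'
#' \deqn{Z(f) = \left[\,j2\pi f C + \sum g_{inst} +
#'   \sum_y \frac{1}{R_y + j2\pi f L_y}\right]^{-1}}
#' with the frequency bridge \eqn{p = j\,2\pi f/1000} (internal time in ms,
#' `f` in Hz).  At `f = 0` the inductors are shorts, so the DC input
#' conductance is \eqn{\sum g_{inst} + \sum 1/R_y}.
#'
#' @param circuit a `linear_circuit` (or `reference_circuit`).
#' @param f frequency vector (Hz), non-negative.
#' @return complex impedance (MΩ), same length as `f`.
#' @export
analytic_impedance <- function(circuit, f) {
  stopifnot(all(f >= 0))
  p <- 2i * pi * f / 1000
  Y <- p * circuit$C + sum(circuit$g_inst)
  for (br in circuit$branches) Y <- Y + 1 / (br$R + p * br$L)
  if (any(Mod(Y) == 0)) stop("impedance singularity: zero total admittance")
  1 / Y
}

#' DC input conductance of a linear circuit (µS)
#' @param circuit a `linear_circuit`.
#' @export
dc_conductance <- function(circuit) {
  sum(circuit$g_inst) + sum(vapply(circuit$branches,
                                   function(b) 1 / b$R, 0))
}

#' Time-domain simulation of the linear circuit
#'
#' RK4 integration of the state-space form of the circuit,
#' \eqn{C\,\dot v = -\sum g\,v - \sum_y I_y + I_{inp}} and
#' \eqn{L_y\,\dot I_y = v - R_y I_y}, from zero initial conditions, where
#' `v` is the voltage deviation from the equilibrium (`V - V*`).  Before
#' integrating, the eigenvalues of the system matrix scaled by `dt` are
#' checked against the RK4 stability region (negative-element branches can
#' destabilize coarse grids).
#'
#' @param circuit a `linear_circuit`.
#' @param stimulus a `pd_stimulus` carrying the *perturbation* current (nA);
#'   do not add the holding current here.
#' @return data.frame with `t` (ms), `v` (mV) and one column per branch
#'   current (nA), class `linear_trace`.
#' @export
simulate_linear <- function(circuit, stimulus) {
  dt <- diff(stimulus$t[1:2])
  if (max(abs(diff(stimulus$t) - dt)) > 1e-9 * dt)
    stop("stimulus grid is not uniform")
  nb <- length(circuit$branches)
  Rb <- vapply(circuit$branches, `[[`, 0, "R")
  Lb <- vapply(circuit$branches, `[[`, 0, "L")
  G <- sum(circuit$g_inst)
  A <- matrix(0, nb + 1, nb + 1)
  A[1, 1] <- -G / circuit$C
  if (nb > 0) {
    A[1, -1] <- -1 / circuit$C
    A[cbind(seq_len(nb) + 1L, 1L)] <- 1 / Lb
    A[cbind(seq_len(nb) + 1L, seq_len(nb) + 1L)] <- -Rb / Lb
  }
  z <- eigen(A, only.values = TRUE)$values * dt
  growth <- Mod(1 + z + z^2 / 2 + z^3 / 6 + z^4 / 24)
  if (any(growth > 1 + 1e-12))
    stop(sprintf("dt = %g ms is outside the RK4 stability region for this circuit (max growth factor %.4f)",
                 dt, max(growth)))
  y <- rk4_linear_cpp(Rb, Lb, circuit$C, G, stimulus$I, dt)
  colnames(y) <- c("v", vapply(circuit$branches, `[[`, "", "label"))
  out <- data.frame(t = stimulus$t, y, check.names = FALSE)
  class(out) <- c("linear_trace", "data.frame")
  attr(out, "dt") <- dt
  out
}

#' Classify an RL branch as resonator or amplifier
#'
#' A branch with positive R and L is inductive: it opposes slow voltage
#' deflections (negative feedback) and forms the high-pass arm of the
#' resonance (resonator).  A branch with negative R and L behaves like a
#' capacitive, positive-feedback element that boosts the impedance
#' (amplifier).  Degenerate pure-resistor branches (L = 0, R > 0) count as
#' resonators; mixed signs are flagged `"unclassified"`.
#'
#' @param branch an `rl_branch`.
#' @return `"resonator"`, `"amplifier"` or `"unclassified"`.
#' @export
classify_branch <- function(branch) {
  R <- branch$R; L <- branch$L
  if (R > 0 && L >= 0) "resonator"
  else if (R < 0 && L < 0) "amplifier"
  else "unclassified"
}

#' Circuit component table
#'
#' One row per component of the equivalent circuit: the inverse instantaneous
#' conductances (`R_<ch>0`) and each branch's R and L.  `convention =
#' "internal"` reports MΩ and MΩ·ms (self-consistent with µS, nF, ms);
#' `"publication"` applies the fixed conversion used by the published
#' component table, whose resistances equal the internal MΩ values divided by
#' 1000 and whose inductances (in H) equal those resistances times the branch
#' time constant in seconds (i.e. internal L/1e6).
#'
#' @param circuit a `linear_circuit`.
#' @param convention `"publication"` (default) or `"internal"`.
#' @return data.frame with columns `channel`, `component`, `R`, `L`,
#'   `class` (resonator/amplifier for branches, NA for instantaneous terms).
#' @export
circuit_component_table <- function(circuit,
                                    convention = c("publication", "internal")) {
  convention <- match.arg(convention)
  sR <- if (convention == "publication") 1e-3 else 1
  sL <- if (convention == "publication") 1e-6 else 1
  rows <- list()
  for (nm in setdiff(names(circuit$g_inst), "leak"))
    rows[[length(rows) + 1L]] <- data.frame(
      channel = nm, component = paste0("R_", nm, "0"),
      R = sR / circuit$g_inst[[nm]], L = NA_real_, class = NA_character_)
  for (br in circuit$branches)
    rows[[length(rows) + 1L]] <- data.frame(
      channel = br$channel, component = br$label,
      R = sR * br$R, L = sL * br$L, class = classify_branch(br))
  out <- do.call(rbind, rows)
  attr(out, "units") <- if (convention == "publication")
    c(R = "MOhm (publication convention)", L = "H (publication convention)")
  else c(R = "MOhm", L = "MOhm*ms")
  out
}

#' @export
print.linear_circuit <- function(x, ...) {
  cat(sprintf("Quasi-active RLC circuit at V* = %g mV: C = %g nF, %d RL branches\n",
              x$V_star, x$C, length(x$branches)))
  cat("  instantaneous conductances (µS):\n")
  print(round(x$g_inst, 6))
  tab <- circuit_component_table(x, "internal")
  tab$R <- signif(tab$R, 5); tab$L <- signif(tab$L, 5)
  print(tab, row.names = FALSE)
  invisible(x)
}
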