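#' Run one chirp-impedance condition
#'
#' End-to-end driver for one experimental condition: apply conductance
#' overrides, equilibrate at each holding potential, deliver the chirp
#' (superimposed on the computed holding current), estimate the impedance
#' profile and resonance metrics.  `model_kind = "nonlinear"` integrates the
#' HH-type model; `"linear"` linearizes at the same equilibrium and simulates
#' the equivalent RLC circuit with the chirp as perturbation.  A failed
#' equilibration or an unstable linear simulation is recorded as a failed row
#' and the run continues.
#'
#' @param params a `pd_params` object (control condition by default).
#' @param V_hold vector of holding potentials (mV).
#' @param overrides named numeric vector of conductance scale factors, e.g.
#'   `c(h = 0)` for an h-channel knockout or `c(KCa = 100)` for the amplified
#'   KCa condition; `"Ca"` scales CaT and CaS together.
#' @param model_kind `"nonlinear"` or `"linear"`.
#' @param chirp chirp stimulus (see [chirp_current()]).
#' @param span smoothing span; default 0.1 for the nonlinear model (harmonic
#'   ripple) and no smoothing for the circuit.
#' @param out_dir optional directory; when given, each condition's profile is
#'   written as CSV with a JSON metrics sidecar.
#' @return data.frame with one row per holding potential: `V_star`, `f_res`,
#'   `Z_max`, `Q`, `is_resonant`, `ok`, `message`.  Attribute `"profiles"`
#'   holds the impedance profiles.
#' @export
run_condition <- function(params = pd_control_params(), V_hold = -55,
                          overrides = NULL,
                          model_kind = c("nonlinear", "linear"),
                          chirp = chirp_current(0.5, 0, 5, 10),
                          span = if (model_kind[1] == "nonlinear") 0.1 else NULL,
                          out_dir = NULL) {
  model_kind <- match.arg(model_kind)
  if (!is.null(overrides))
    params <- scale_conductance(params, names(overrides), unname(overrides))
  rows <- vector("list", length(V_hold))
  profiles <- vector("list", length(V_hold))
  for (i in seq_along(V_hold)) {
    V <- V_hold[i]
    res <- tryCatch({
      eq <- find_equilibrium(params, V)
      pr <- if (model_kind == "nonlinear") {
        tr <- integrate_pd(params, offset_stimulus(chirp, eq$I_hold), eq)
        trace_impedance(tr, span = span)
      } else {
        circ <- assemble_linear_circuit(params, eq)
        tr <- simulate_linear(circ, chirp)
        trace_impedance(tr, stimulus = chirp, span = span)
      }
      m <- get_metrics(pr)
      profiles[[i]] <- pr
      data.frame(V_star = V, f_res = m$f_res, Z_max = m$Z_max, Q = m$Q,
                 is_resonant = m$is_resonant, ok = TRUE, message = "")
    }, error = function(e)
      data.frame(V_star = V, f_res = NA_real_, Z_max = NA_real_, Q = NA_real_,
                 is_resonant = NA, ok = FALSE, message = conditionMessage(e)))
    rows[[i]] <- res
    if (!is.null(out_dir) && res$ok) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_profile_csv(profiles[[i]],
                        file.path(out_dir, sprintf("profile_%s_%+.0fmV.csv",
                                                   model_kind, V)))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- profiles
  attr(out, "condition") <- list(model_kind = model_kind,
                                 overrides = overrides,
                                 I_amp = attr(chirp, "I_amp"))
  out
}

#' Holding-potential sweep
#'
#' Runs the chirp-impedance pipeline over a grid of holding potentials and
#' tabulates the resonance metrics — the material of the Z-f surface and the
#' Q-V curve (U-shaped under control conditions, with maximal peak impedance
#' near −55 mV).
#'
#' @inheritParams run_condition
#' @param potentials holding potentials (mV), at least two.
#' @return data.frame `(V_star, f_res, Z_max, Q, is_resonant, ok, message)`.
#' @export
sweep_resting_potential <- function(params = pd_control_params(),
                                    potentials = seq(-64, -49, by = 1),
                                    model_kind = "nonlinear",
                                    chirp = chirp_current(0.5, 0, 5, 10),
                                    ...) {
  stopifnot(length(potentials) >= 2)
  run_condition(params, V_hold = potentials, model_kind = model_kind,
                chirp = chirp, ...)
}

#' Conductance sweep
#'
#' Scales one channel's maximal conductance through `factors` (0 = knockout)
#' and records the resonance metrics at a fixed holding potential, by default
#' on the linearized-circuit path.
#'
#' @inheritParams run_condition
#' @param channel channel name (`"h"`, `"CaT"`, `"CaS"`, `"KCa"`, `"Ca"`).
#' @param factors non-negative scale factors.
#' @param V_star holding potential (mV).
#' @return data.frame `(factor, f_res, Z_max, Q, is_resonant, ok, message)`.
#' @export
sweep_conductance <- function(params = pd_control_params(), channel, factors,
                              V_star = -55, model_kind = "linear",
                              chirp = chirp_current(0.5, 0, 5, 10), ...) {
  stopifnot(all(factors >= 0))
  rows <- lapply(factors, function(fac) {
    r <- run_condition(params, V_hold = V_star,
                       overrides = stats::setNames(fac, channel),
                       model_kind = model_kind, chirp = chirp, ...)
    cbind(factor = fac, r[, setdiff(names(r), "V_star")])
  })
  do.call(rbind, rows)
}

#' Reproduce the circuit component table at the control rest
#'
#' Linearizes the control model at `V_star` and returns the component table
#' in the publication convention (see [circuit_component_table()]):
#' one row per instantaneous resistance and per RL branch, with
#' amplifier/resonator classification.  Under control parameters the
#' negative-element branches are exactly `m_CaT`, `m_CaS` and `KCa1`.
#'
#' @param params a `pd_params` object.
#' @param V_star linearization potential (mV).
#' @param convention `"publication"` or `"internal"`.
#' @inheritParams linearize_channel
#' @return the component table data.frame.
#' @export
reproduce_table3 <- function(params = pd_control_params(), V_star = -55,
                             convention = "publication", dca_scale = 1000) {
  eq <- find_equilibrium(params, V_star)
  circ <- assemble_linear_circuit(params, eq, dca_scale = dca_scale)
  circuit_component_table(circ, convention)
}

#' The amplified-KCa experiment
#'
#' Multiplies the KCa maximal conductance (×100 by default), which shrinks
#' the inductance of the KCa resonator branches and moves the resonance into
#' a range where it survives an h-channel knockout — the manipulation that
#' separates the resonator role of KCa from the amplifier role of the calcium
#' currents.  Returns metrics for the four knockout conditions at the
#' hyperpolarized and depolarized reference potentials.
#'
#' @inheritParams run_condition
#' @param factor KCa conductance multiplier.
#' @param V_hyper,V_depol reference potentials (mV).
#' @return data.frame with columns `condition`, `V_star`, `f_res`, `Z_max`,
#'   `Q`, `is_resonant`, `ok`, `message`.
#' @export
amplified_kca <- function(params = pd_control_params(), factor = 100,
                          V_hyper = -80, V_depol = -53,
                          model_kind = "linear",
                          chirp = chirp_current(0.5, 0, 5, 10), ...) {
  base <- scale_conductance(params, "KCa", factor)
  conds <- list(control = NULL, no_h = c(h = 0), no_Ca = c(Ca = 0))
  rows <- list()
  for (nm in names(conds)) {
    r <- run_condition(base, V_hold = c(V_hyper, V_depol),
                       overrides = conds[[nm]], model_kind = model_kind,
                       chirp = chirp, ...)
    rows[[nm]] <- cbind(condition = nm, r)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
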