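test_that("gating steady states hit their midpoints and printed forms", {
  # published sigmoid parameterizations, evaluated against the raw formulas
  gk <- gating_kinetics(-48.5, 4.8, 50, 200, -42.2, -8.73)
  expect_equal(gate_inf(gk, -48.5), 0.5)
  expect_equal(gate_tau(gk, -42.2), 50 + 200 / 2)

  p <- pd_control_params()
  caT <- p$channels$CaT
  ss <- eval_steady_state(caT, -25)
  expect_equal(ss$m_inf, 0.5)
  expect_equal(ss$h_inf, 1 / (1 + exp(11 / 7)))
  tc <- eval_time_constants(caT, -50)
  expect_equal(tc$tau_h, 80 + 10 / 2)
  expect_equal(eval_time_constants(caT, -58)$tau_m, 1 + 9 / 2)
})

test_that("steady states stay in [0,1] and time constants positive over the range", {
  p <- pd_control_params()
  V <- seq(-100, 0, by = 0.5)
  for (ch in p$channels) {
    m <- gate_inf(ch$activation, V)
    expect_true(all(m >= 0 & m <= 1))
    expect_true(all(gate_tau(ch$activation, V) > 0))
    if (!is.null(ch$inactivation)) {
      expect_true(all(gate_inf(ch$inactivation, V) >= 0 &
                        gate_inf(ch$inactivation, V) <= 1))
      expect_true(all(gate_tau(ch$inactivation, V) > 0))
    }
  }
})

test_that("KCa activation carries the saturating calcium factor", {
  p <- pd_control_params()
  kca <- p$channels$KCa
  expect_equal(eval_steady_state(kca, -40, Ca = 0)$m_inf, 0)
  # product form: calcium factor times the voltage sigmoid
  s_v <- 1 / (1 + exp(-(-40 + 51) / 8))
  expect_equal(eval_steady_state(kca, -40, Ca = 30, Kd = 30)$m_inf, 0.5 * s_v)
  expect_error(eval_steady_state(kca, -40, Ca = -1), "negative calcium")
})

test_that("channel current follows gbar m^r h^q (V - E), positive outward", {
  p <- pd_control_params()
  expect_equal(channel_current(p$channels$CaS, -50, m = 0), 0)
  h <- p$channels$h
  expect_equal(channel_current(h, h$reversal, m = 0.7), 0)
  unit <- channel_spec("u", 1, -10, 3L,
                       activation = gating_kinetics(-50, -5, 1, 1, -50, 5),
                       inactivation = gating_kinetics(-50, 5, 1, 1, -50, 5))
  expect_equal(channel_current(unit, 0, m = 1, h = 1), 10)
})

test_that("calcium fixed point matches its defining arithmetic and the relaxed ODE", {
  p0 <- scale_conductance(pd_control_params(), c("CaT", "CaS"), 0)
  expect_equal(calcium_steady_state(p0, -55), 0.5)

  p <- pd_control_params()
  V <- -55
  ICa <- 0
  for (nm in c("CaT", "CaS")) {
    ch <- p$channels[[nm]]
    ss <- eval_steady_state(ch, V)
    ICa <- ICa + channel_current(ch, V, ss$m_inf,
                                 if (is.null(ss$h_inf)) 1 else ss$h_inf)
  }
  expect_lt(ICa, 0)                       # inward at subthreshold potentials
  expect_equal(calcium_steady_state(p, V), 0.5 - 0.515 * ICa)
  expect_gte(calcium_steady_state(p, V), p$calcium$C0)

  # relax d[Ca]/dt at clamped V by RK4 and compare with the closed form
  Ca <- 10; dt <- 1
  f <- function(x) (-p$calcium$F * ICa - x + p$calcium$C0) / p$calcium$tau_Ca
  for (i in 1:8000) {
    k1 <- f(Ca); k2 <- f(Ca + dt / 2 * k1); k3 <- f(Ca + dt / 2 * k2)
    k4 <- f(Ca + dt * k3)
    Ca <- Ca + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_lt(abs(Ca - calcium_steady_state(p, V)), 1e-6)
})

test_that("the right-hand side vanishes at equilibria and sums its currents", {
  p <- pd_control_params()
  eq <- find_equilibrium(p, -55)
  expect_lt(max(abs(model_rhs(eq$state, eq$I_hold, p))), 1e-9)

  # independent term-by-term sum of the voltage equation
  st <- pd_state(-60, 0.3, 0.1, 0.8, 0.05, 0.01, 1.2)
  terms <- vapply(p$channels, function(ch) {
    m <- st[[paste0("m_", ch$name)]]
    h <- if (ch$q == 1L) st[[paste0("h_", ch$name)]] else 1
    channel_current(ch, st[["V"]], m, h)
  }, 0)
  dV_hand <- (-p$g_leak * (st[["V"]] - p$E_leak) - sum(terms) + 0.7) / p$C
  expect_equal(model_rhs(st, 0.7, p)[["V"]], dV_hand)
})

test_that("with all active conductances zero the membrane is a passive RC", {
  p <- scale_conductance(pd_control_params(), c("h", "CaT", "CaS", "KCa"), 0)
  st <- function(V) pd_state(V, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  expect_equal(model_rhs(st(p$E_leak), 0, p)[["V"]], 0)
  dv <- vapply(c(-80, -60, -40), function(V) model_rhs(st(V), 0, p)[["V"]], 0)
  # linear in V: second difference vanishes
  expect_equal(dv[1] - 2 * dv[2] + dv[3], 0, tolerance = 1e-12)
})

test_that("gating variables remain in [0,1] along simulated trajectories", {
  p <- pd_control_params()
  eq <- find_equilibrium(p, -55)
  ch <- chirp_current(2, 0, 5, 2, pad = 0)   # large drive, short record
  tr <- integrate_pd(p, offset_stimulus(ch, eq$I_hold), eq)
  g <- as.matrix(tr[, c("m_h", "m_CaT", "h_CaT", "m_CaS", "m_KCa")])
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(tr$Ca >= 0))
})

test_that("parameters survive a config round trip and reproduce control exactly", {
  p <- pd_control_params()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_pd_params(p, tmp)
  q <- read_pd_params(tmp)
  expect_equal(q$E_leak, p$E_leak)
  expect_equal(unclass(find_equilibrium(q, -55)$state),
               unclass(find_equilibrium(p, -55)$state))
  ctrl <- read_pd_params(system.file("extdata", "control.yaml",
                                     package = "pdresonance"))
  expect_equal(ctrl$channels$KCa$gbar, 150)
  expect_equal(find_equilibrium(ctrl, ctrl$V_rest)$I_hold, 0, tolerance = 1e-9)
  expect_error(read_pd_params(withr::local_tempfile(lines = "nonsense_key: 1",
                                                    fileext = ".yaml")),
               "unknown config keys")
})
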