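p_ctrl <- pd_control_params()
eq55 <- find_equilibrium(p_ctrl, -55)

test_that("the full control model linearizes to exactly nine labelled branches", {
  circ <- assemble_linear_circuit(p_ctrl, eq55)
  labs <- vapply(circ$branches, `[[`, "", "label")
  expect_equal(labs, c("m_CaT", "h_CaT", "m_CaS", "m_h", paste0("KCa", 1:5)))
  expect_equal(sort(names(circ$g_inst)), sort(c("leak", "h", "CaT", "CaS", "KCa")))
})

test_that("sign structure at the control rest: calcium activation and KCa1 negative", {
  tab <- circuit_component_table(assemble_linear_circuit(p_ctrl, eq55))
  neg <- tab$component[!is.na(tab$class) & tab$class == "amplifier"]
  expect_setequal(neg, c("m_CaT", "m_CaS", "KCa1"))
  pos <- tab$component[!is.na(tab$class) & tab$class == "resonator"]
  expect_setequal(pos, c("h_CaT", "m_h", paste0("KCa", 2:5)))
  # amplifying signs trace back to V* - E_Ca < 0
  expect_lt(eq55$V_star - p_ctrl$E_Ca, 0)
  with(tab[tab$component == "m_CaT", ], { expect_lt(R, 0); expect_lt(L, 0) })
})

test_that("knocking a channel out before or after linearization is the same", {
  p_noh <- scale_conductance(p_ctrl, "h", 0)
  eq <- find_equilibrium(p_noh, -55)
  circ_ko <- assemble_linear_circuit(p_noh, eq)
  labs <- vapply(circ_ko$branches, `[[`, "", "label")
  expect_false("m_h" %in% labs)
  expect_false("h" %in% names(circ_ko$g_inst))
  # remaining branches must be identical to dropping m_h from the control
  # circuit built at the same equilibrium
  circ_full <- assemble_linear_circuit(p_ctrl, find_equilibrium(p_ctrl, -55))
  keep <- vapply(circ_full$branches, `[[`, "", "label") != "m_h"
  # equilibria differ only through channels whose gating ignores h, so the
  # non-h branch values coincide exactly
  for (i in seq_along(circ_ko$branches)) {
    a <- circ_ko$branches[[i]]; b <- circ_full$branches[keep][[i]]
    expect_equal(a$R, b$R); expect_equal(a$L, b$L)
  }
})

test_that("a calcium knockout silences the KCa feedback branches", {
  p_noca <- scale_conductance(p_ctrl, "Ca", 0)
  circ <- assemble_linear_circuit(p_noca, find_equilibrium(p_noca, -55))
  labs <- vapply(circ$branches, `[[`, "", "label")
  # only the voltage path of KCa survives; all calcium-feedback terms vanish
  expect_setequal(labs, c("m_h", "KCa1"))
})

test_that("branch admittances reproduce the rational small-signal admittance", {
  set.seed(1)
  f <- sort(stats::runif(20, 0.05, 5))
  pval <- 2i * pi * f / 1000
  for (sc in c(1, 1000)) {
    circ <- assemble_linear_circuit(p_ctrl, eq55, dca_scale = sc)
    Z <- analytic_impedance(circ, f)
    Y_ref <- direct_admittance(p_ctrl, eq55, pval, dca_scale = sc)
    expect_equal(1 / Z, Y_ref, tolerance = 1e-10)
  }
})

test_that("the self-consistent circuit's DC conductance equals the I-V slope", {
  for (V in c(-80, -64, -55, -50)) {
    eq <- find_equilibrium(p_ctrl, V)
    circ <- assemble_linear_circuit(p_ctrl, eq, dca_scale = 1)
    dV <- 1e-3
    slope <- (steady_iv(p_ctrl, V + dV) - steady_iv(p_ctrl, V - dV)) / (2 * dV)
    expect_equal(dc_conductance(circ), slope, tolerance = 1e-6)
  }
})

test_that("analytic impedance has the right DC and capacitive limits", {
  circ <- assemble_linear_circuit(p_ctrl, eq55)
  Z0 <- analytic_impedance(circ, 0)
  expect_equal(Im(Z0), 0)
  expect_equal(Re(Z0), 1 / dc_conductance(circ))
  f_hi <- 1e6
  expect_equal(Mod(analytic_impedance(circ, f_hi)) *
                 (2 * pi * f_hi / 1000 * circ$C), 1, tolerance = 1e-4)
  expect_error(analytic_impedance(circ, -1))
})

test_that("the simulated circuit matches its closed-form impedance", {
  circ <- assemble_linear_circuit(p_ctrl, eq55)
  ch <- chirp_current(0.1, 0, 5, 10)
  tr <- simulate_linear(circ, ch)
  expect_equal(tr$v[1], 0)
  pr <- trace_impedance(tr, ch, span = NULL)
  sel <- pr$f >= 0.1 & pr$f <= 5
  Zc <- Mod(analytic_impedance(circ, pr$f[sel]))
  expect_lt(max(abs(pr$magnitude[sel] - Zc) / Zc), 0.01)
})

test_that("zero stimulus produces an identically zero circuit response", {
  circ <- assemble_linear_circuit(p_ctrl, eq55)
  tr <- simulate_linear(circ, dc_current(0, 1))
  expect_true(all(tr$v == 0))
})

test_that("a branchless circuit steps like an RC with tau = C/g", {
  circ <- structure(list(C = 2, g_inst = c(leak = 0.1), branches = list(),
                         V_star = NA_real_), class = "linear_circuit")
  tr <- simulate_linear(circ, dc_current(1, 1))
  expect_equal(tr$v, (1 / 0.1) * (1 - exp(-tr$t / (2 / 0.1))), tolerance = 1e-8)
})

test_that("the stability pre-check rejects steps outside the RK4 region", {
  circ <- structure(list(C = 1, g_inst = c(leak = 0.1),
                         branches = list(rl_branch("fast", 1, 0.005)),
                         V_star = NA_real_), class = "linear_circuit")
  expect_error(simulate_linear(circ, dc_current(0.1, 0.01)), "stability")
})

test_that("branches classify by their element signs", {
  expect_equal(classify_branch(rl_branch("a", 17.7, 5.3)), "resonator")
  expect_equal(classify_branch(rl_branch("b", -2.98, -0.0152)), "amplifier")
  expect_equal(classify_branch(rl_branch("c", 1, 0)), "resonator")
  expect_equal(classify_branch(rl_branch("d", -1, 2)), "unclassified")
})

test_that("small-signal impedance of the nonlinear model matches the circuit", {
  ch <- chirp_current(0.05, 0, 5, 10)   # well inside the linear regime
  trN <- run_chirp_nonlinear(p_ctrl, -55, ch)
  prN <- trace_impedance(trN, span = NULL)
  circ <- assemble_linear_circuit(p_ctrl, eq55)
  sel <- prN$f >= 0.1 & prN$f <= 2
  Zc <- Mod(analytic_impedance(circ, prN$f[sel]))
  expect_lt(max(abs(prN$magnitude[sel] - Zc) / Zc), 0.05)
})

test_that("an equilibrium from mismatched parameters is refused", {
  p2 <- scale_conductance(p_ctrl, "h", 2)
  expect_error(assemble_linear_circuit(p2, eq55), "inconsistent")
})

test_that("publication-convention components scale fixedly from internal ones", {
  int <- circuit_component_table(assemble_linear_circuit(p_ctrl, eq55),
                                 "internal")
  pub <- circuit_component_table(assemble_linear_circuit(p_ctrl, eq55),
                                 "publication")
  expect_equal(pub$R, int$R / 1e3)
  expect_equal(pub$L, int$L / 1e6)
})
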