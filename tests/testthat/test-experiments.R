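p_ctrl <- pd_control_params()

test_that("the control condition at rest is resonant on both model paths", {
  rN <- run_condition(p_ctrl, -55)
  rL <- run_condition(p_ctrl, -55, model_kind = "linear")
  expect_true(rN$ok && rL$ok)
  expect_true(rN$is_resonant && rL$is_resonant)
  expect_gt(rN$f_res, 0.5); expect_lt(rN$f_res, 3)
  expect_equal(rN$f_res, rL$f_res, tolerance = 0.15)
})

test_that("nonlinear and linear paths agree on resonance across the rest range", {
  Vs <- c(-60, -55, -52, -50)
  rN <- run_condition(p_ctrl, Vs)
  rL <- run_condition(p_ctrl, Vs, model_kind = "linear")
  expect_equal(rN$is_resonant, rL$is_resonant)
})

test_that("failed conditions are recorded without aborting the run", {
  r <- run_condition(p_ctrl, c(-55, -30))   # -30 mV is outside the range
  expect_true(r$ok[1]); expect_false(r$ok[2])
  expect_match(r$message[2], ".+")
  expect_true(is.na(r$Q[2]))
})

test_that("h-channel knockout abolishes the hyperpolarized resonance", {
  ctrl <- run_condition(p_ctrl, -80)
  ko <- run_condition(p_ctrl, -80, overrides = c(h = 0))
  expect_true(ctrl$is_resonant)
  expect_false(ko$is_resonant)
  expect_lt(ko$Q, 1.01)
})

test_that("calcium knockout leaves the hyperpolarized profile untouched", {
  pr1 <- attr(run_condition(p_ctrl, -80), "profiles")[[1]]
  pr2 <- attr(run_condition(p_ctrl, -80, overrides = c(Ca = 0)),
              "profiles")[[1]]
  sel <- pr1$f >= 0.1 & pr1$f <= 5
  expect_lt(max(abs(pr1$mag_smooth[sel] - pr2$mag_smooth[sel]) /
                  pr1$mag_smooth[sel]), 0.02)
})

test_that("the holding-potential sweep tabulates one row per potential", {
  sw <- sweep_resting_potential(p_ctrl, potentials = c(-60, -57, -55))
  expect_equal(sw$V_star, c(-60, -57, -55))
  expect_true(all(sw$ok))
  # Q falls toward the resting potential from the hyperpolarized side
  expect_true(all(diff(sw$Q) < 0))
  expect_error(sweep_resting_potential(p_ctrl, potentials = -55))
})

test_that("conductance sweeps show the h-current's resonator signature", {
  sw <- sweep_conductance(p_ctrl, "h", c(0, 1, 2), V_star = -80)
  expect_false(sw$is_resonant[1])            # knockout: no resonance
  expect_true(all(sw$is_resonant[-1]))
  expect_gt(sw$f_res[3], sw$f_res[2])        # more g_h, higher f_res
  expect_lt(sw$Z_max[3], sw$Z_max[2])        # and a damped peak
})

test_that("raising the calcium conductance amplifies the peak impedance", {
  sw <- sweep_conductance(p_ctrl, "Ca", c(0.5, 1, 1.5), V_star = -55)
  expect_true(all(diff(sw$Z_max) > 0))
})

test_that("raising g_KCa strengthens and right-shifts the resonance", {
  sw <- sweep_conductance(p_ctrl, "KCa", c(1, 50, 100), V_star = -55)
  expect_true(all(diff(sw$Q) > 0))
  expect_true(all(diff(sw$f_res) > 0))
  expect_true(all(diff(sw$Z_max) > 0))
})

test_that("the component table mirrors the published layout and signs", {
  tab <- reproduce_table3(p_ctrl)
  expect_equal(tab$component,
               c("R_CaT0", "R_CaS0", "R_h0", "R_KCa0",
                 "m_CaT", "h_CaT", "m_CaS", "m_h", paste0("KCa", 1:5)))
  signs <- sign(tab$R[match(c("KCa1", "m_CaT", "m_CaS"), tab$component)])
  expect_equal(signs, c(-1, -1, -1))
  expect_true(all(tab$R[match(c("h_CaT", "m_h", paste0("KCa", 2:5)),
                              tab$component)] > 0))
  expect_true(all(tab$R[1:4] > 0))
})

test_that("the amplified-KCa experiment keeps its hyperpolarized structure", {
  res <- amplified_kca(p_ctrl)
  expect_true(all(res$ok))
  expect_equal(nrow(res), 6)
  hyp <- res[res$V_star == -80, ]
  expect_true(hyp$is_resonant[hyp$condition == "control"])
  expect_false(hyp$is_resonant[hyp$condition == "no_h"])       # h is the resonator
  expect_equal(hyp$Q[hyp$condition == "no_Ca"],
               hyp$Q[hyp$condition == "control"], tolerance = 0.01)
})

test_that("condition outputs can be written as CSV plus JSON sidecars", {
  out <- withr::local_tempdir()
  run_condition(p_ctrl, -55, out_dir = out)
  csvs <- list.files(out, pattern = "\\.csv$")
  expect_length(csvs, 1)
  js <- jsonlite::read_json(file.path(out, paste0(csvs, ".metrics.json")))
  expect_true(js$is_resonant)
  expect_true(is.numeric(js$Q))
})
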