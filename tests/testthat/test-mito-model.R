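test_that("ATP production factor matches the closed form", {
  expect_equal(atp_production_factor(structural_params(1, 0, 0, 0)), 1)
  expect_equal(atp_production_factor(structural_params(1, 1, 1, 0)), 1)
  # OVCAR3 +S ultrastructure
  expect_equal(atp_production_factor(structural_params(1, 0.28, 0.62, 0.99)),
               (0.28 + exp(0.99)) / 1.62)
})

test_that("degenerate or invalid structural parameters are rejected", {
  expect_error(structural_params(0, 1, 0, 1), "c_w \\+ c_jw")
  expect_error(structural_params(-0.1, 1, 1, 1), "c_w")
  expect_error(structural_params(NA, 1, 1, 1), "finite")
})

test_that("theta is monotone in each structural argument", {
  set.seed(11)
  for (i in 1:200) {
    b <- runif(4, 0.05, 2)  # c_w, c_n, c_jw, m_p
    d <- runif(1, 0.01, 0.5)
    th <- function(cw, cn, cjw, mp)
      atp_production_factor(structural_params(cw, cn, cjw, mp))
    base <- th(b[1], b[2], b[3], b[4])
    expect_gt(th(b[1], b[2] + d, b[3], b[4]), base)
    expect_gt(th(b[1], b[2], b[3], b[4] + d), base)
    expect_lt(th(b[1] + d, b[2], b[3], b[4]), base)
    expect_lt(th(b[1], b[2], b[3] + d, b[4]), base)
  }
})

test_that("fusion and fission rates scale base rates by promoter levels", {
  expect_equal(fusion_rate(1, 0.5), 0.5)
  expect_equal(fusion_rate(0, 1), 0)
  expect_equal(fusion_rate(2, 0.93), 1.86)  # OVMZ6 +S OPA1
  expect_equal(fission_rate(1, 0.31), 0.31) # OVCAR3 +S DRP1
  expect_equal(fission_rate(0, 1), 0)
  expect_equal(fission_rate(1, 1), 1)       # A4 +S DRP1
  expect_error(fusion_rate(-1, 1), ">= 0")
  expect_error(fission_rate(1, -0.2), ">= 0")
})

test_that("biogenesis balances mitophagy in balance mode", {
  cs <- dynamics_constants(M_H = 0.3, M_D = 0.3)
  expect_equal(biogenesis_rate(system_state(1, 1, 1, 1, 0), cs), 0.3 / 2)
  cs2 <- dynamics_constants(M_H = 0.1, M_D = 0.5)
  expect_equal(biogenesis_rate(system_state(0, 0, 3, 2, 1), cs2), 0)
  expect_equal(biogenesis_rate(system_state(2, 1, 1, 0, 0), cs2), 0.7 / 4)
  # degenerate empty system
  expect_equal(biogenesis_rate(c(n_hu = 0, n_du = 0, n_hf = 0, n_df = 0,
                                 atp = 0), cs2), 0)
  # constant mode ignores the state
  csc <- dynamics_constants(biogenesis_mode = "constant", B_const = 0.42)
  expect_equal(biogenesis_rate(system_state(5, 0, 0, 0, 1), csc), 0.42)
})

test_that("state derivative reproduces the hand-evaluated special cases", {
  cs <- dynamics_constants(stress = 0)
  sc <- scenario_params("OVCAR3", "+S", structural_params(1, 0.28, 0.62, 0.99),
                        opa1 = 0.02, drp1 = 0.31, constants = cs)
  # empty system: only the constant ATP drain survives
  d0 <- state_derivative(c(n_hu = 0, n_du = 0, n_hf = 0, n_df = 0, atp = 0), sc)
  expect_equal(unname(d0), c(0, 0, 0, 0, -cs$mu))

  # reference initial conditions: every [ATP]-proportional term vanishes
  d1 <- state_derivative(default_initial_state(), sc)
  B <- (cs$M_H + cs$M_D) / 4
  theta <- atp_production_factor(sc$structural)
  expect_equal(d1[["n_hu"]], B - cs$M_H)
  expect_equal(d1[["n_du"]], B - cs$M_D)
  expect_equal(d1[["n_hf"]], B)
  expect_equal(d1[["n_df"]], B)
  expect_equal(d1[["atp"]],
               theta * (cs$epsilon + 1) * (cs$alpha + 1) - cs$mu)
})

test_that("symmetric parameters give symmetric healthy/deviant derivatives", {
  cs <- dynamics_constants(M_H = 0.2, M_D = 0.2, alpha = 1, stress = 1)
  sc <- scenario_params("A4", "SS", structural_params(0.18, 0.97, 0.34, 0.65),
                        opa1 = 0.65, drp1 = 0.98, constants = cs)
  d <- state_derivative(system_state(0.7, 0.7, 1.3, 1.3, 2.5), sc)
  expect_identical(d[["n_hu"]], d[["n_du"]])
  expect_identical(d[["n_hf"]], d[["n_df"]])
})

test_that("fusion/fission are one-to-one conversions: population change equals net biogenesis", {
  set.seed(21)
  for (i in 1:50) {
    cs <- dynamics_constants(F_0 = runif(1, 0, 2), K_0 = runif(1, 0, 2),
                             M_H = runif(1, 0, 1), M_D = runif(1, 0, 1),
                             alpha = 1 + runif(1), epsilon = 1 + runif(1),
                             mu = runif(1, 0, 5), stress = runif(1, 0, 3),
                             biogenesis_mode = sample(c("balance", "constant"), 1),
                             B_const = runif(1, 0, 0.5))
    sc <- scenario_params("OVMZ6", "SS",
                          structural_params(runif(1, 0.1, 1), runif(1, 0, 1),
                                            runif(1, 0.1, 1), runif(1, 0, 1)),
                          opa1 = runif(1), drp1 = runif(1), constants = cs,
                          allow_zero_stress = TRUE)
    y <- system_state(runif(1, 0, 3), runif(1, 0, 3), runif(1, 0, 3),
                      runif(1, 0, 3), runif(1, 0, 10))
    d <- state_derivative(y, sc)
    B <- biogenesis_rate(y, cs)
    total <- sum(unclass(y)[1:4])
    expected <- B * total - cs$M_H * y[["n_hu"]] - cs$M_D * y[["n_du"]]
    expect_equal(sum(d[1:4]), expected, tolerance = 1e-12)
    if (cs$biogenesis_mode == "balance") {
      expect_equal(sum(d[1:4]), 0, tolerance = 1e-12)
    }
  }
})

test_that("swapping healthy and deviant pools with their mitophagy rates mirrors the dynamics", {
  st <- structural_params(0.5, 0.6, 0.4, 0.7)
  y <- system_state(0.9, 1.7, 2.1, 0.3, 4.2)
  y_swap <- system_state(1.7, 0.9, 0.3, 2.1, 4.2)
  cs <- dynamics_constants(M_H = 0.15, M_D = 0.45, alpha = 1, stress = 2)
  cs_swap <- dynamics_constants(M_H = 0.45, M_D = 0.15, alpha = 1, stress = 2)
  sc <- scenario_params("CAOV3", "SS", st, opa1 = 0.4, drp1 = 0.3,
                        constants = cs)
  sc_swap <- scenario_params("CAOV3", "SS", st, opa1 = 0.4, drp1 = 0.3,
                             constants = cs_swap)
  d <- state_derivative(y, sc)
  d_swap <- state_derivative(y_swap, sc_swap)
  expect_equal(d_swap[["atp"]], d[["atp"]])
  expect_equal(d_swap[["n_hu"]], d[["n_du"]])
  expect_equal(d_swap[["n_du"]], d[["n_hu"]])
  expect_equal(d_swap[["n_hf"]], d[["n_df"]])
  expect_equal(d_swap[["n_df"]], d[["n_hf"]])
})

test_that("zero stress is the serum-fed limit of the stressed equations", {
  st <- structural_params(0.23, 1, 0.47, 0.32)
  y <- system_state(1.2, 0.8, 1.5, 0.5, 3)
  sc_s <- scenario_params("OVCA420", "+S", st, opa1 = 0.04, drp1 = 0.13,
                          constants = dynamics_constants(stress = 0))
  sc_ss0 <- scenario_params("OVCA420", "SS", st, opa1 = 0.04, drp1 = 0.13,
                            constants = dynamics_constants(stress = 0),
                            allow_zero_stress = TRUE)
  expect_identical(state_derivative(y, sc_s), state_derivative(y, sc_ss0))
})

test_that("efficiency factors below 1 and invalid states are rejected", {
  expect_error(dynamics_constants(alpha = 0.5), "alpha")
  expect_error(dynamics_constants(epsilon = 0.9), "epsilon")
  expect_error(dynamics_constants(M_H = -0.1), "M_H")
  expect_error(system_state(1, 1, -1, 1, 0), "n_hf")
  expect_warning(
    scenario_params("A4", "SS", structural_params(1, 1, 1, 1),
                    opa1 = 1, drp1 = 1,
                    constants = dynamics_constants(stress = 0)),
    "stress = 0")
})
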