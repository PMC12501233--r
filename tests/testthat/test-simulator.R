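test_that("decoupled linear limit integrates to ATP(t) = t exactly", {
  cs <- dynamics_constants(F_0 = 0, K_0 = 0, M_H = 0, M_D = 0,
                           alpha = 1, epsilon = 1, mu = 3)
  tr <- integrate_scenario(theta_one_scenario(cs),
                           settings = solver_settings(t_end = 10))
  expect_equal(tr$states[, "atp"], tr$times, tolerance = 1e-9)
  for (cl in c("n_hu", "n_du", "n_hf", "n_df")) {
    expect_equal(tr$states[, cl], rep(1, length(tr$times)), tolerance = 1e-9)
  }
})

test_that("a zero-length time span returns the initial state", {
  sc <- theta_one_scenario(dynamics_constants())
  y0 <- system_state(2, 1, 0.5, 0.25, 7)
  tr <- integrate_scenario(sc, initial = y0,
                           settings = solver_settings(t_start = 3, t_end = 3))
  expect_length(tr$times, 1)
  expect_equal(unname(tr$states[1, ]), unname(unclass(y0)))
})

test_that("packaged presets reproduce the phenotype parameter table", {
  presets <- load_presets()
  expect_equal(nrow(presets), 10)
  a4 <- presets[presets$cell_line == "A4" & presets$condition == "+S", ]
  expect_equal(unname(unlist(a4[, c("c_w", "c_n", "c_jw", "m_p", "opa1", "drp1")])),
               c(0.44, 0.54, 0.63, 0.54, 0.44, 1))
  ovmz6_ss <- presets[presets$cell_line == "OVMZ6" & presets$condition == "SS", ]
  expect_equal(ovmz6_ss$opa1, 1)
  expect_equal(ovmz6_ss$drp1, 0.16)
  ovcar3_s <- presets[presets$cell_line == "OVCAR3" & presets$condition == "+S", ]
  expect_equal(unname(unlist(ovcar3_s[, c("c_w", "c_n", "c_jw", "m_p")])),
               c(1, 0.28, 0.62, 0.99))
})

test_that("the incomplete OVCAR3 SS row is refused unless explicitly filled", {
  presets <- load_presets()
  row <- presets[presets$cell_line == "OVCAR3" & presets$condition == "SS", ]
  expect_true(is.na(row$m_p))
  expect_error(scenario_from_preset(row), "m_p")
  expect_error(scenario_from_preset(row), "fill_missing")

  expect_message(filled <- load_presets(fill_missing = TRUE), "OVCAR3 SS m_p")
  row_f <- filled[filled$cell_line == "OVCAR3" & filled$condition == "SS", ]
  expect_equal(row_f$m_p, 0.99)  # reused from the OVCAR3 +S row
  expect_equal(attr(filled, "filled")$field, "m_p")
  expect_s3_class(scenario_from_preset(row_f), "scenario_params")
})

test_that("preset schema violations are reported with offending rows", {
  tmp <- tempfile(fileext = ".csv")
  writeLines("cell_line,condition,c_w,c_n,c_jw,m_p,opa1", tmp)
  expect_error(load_presets(tmp), "missing column")
  writeLines(c("cell_line,condition,c_w,c_n,c_jw,m_p,opa1,drp1"), tmp)
  expect_error(load_presets(tmp), "no data rows")
  writeLines(c("cell_line,condition,c_w,c_n,c_jw,m_p,opa1,drp1",
               "A4,+S,0.4,abc,0.6,0.5,0.4,1"), tmp)
  expect_error(load_presets(tmp), "non-numeric")
  writeLines(c("cell_line,condition,c_w,c_n,c_jw,m_p,opa1,drp1",
               "A4,starved,0.4,0.5,0.6,0.5,0.4,1"), tmp)
  expect_error(load_presets(tmp), "\\+S")
  writeLines(c("cell_line,condition,c_w,c_n,c_jw,m_p,opa1,drp1",
               "A4,+S,0.4,0.5,0.6,0.5,-0.4,1"), tmp)
  expect_error(load_presets(tmp), "negative")
  expect_error(load_presets(tempfile()), "not found")
})

test_that("the panel covers all scenarios, errors on missing pairs, and is deterministic", {
  presets <- presets_filled()
  settings <- solver_settings(t_end = 2, n_out = 41)
  panel <- run_panel(presets, settings)
  expect_length(panel, 10)
  expect_setequal(names(panel),
                  as.vector(outer(unique(presets$cell_line),
                                  c("+S", "SS"), paste)))
  small <- run_panel(presets, settings, cell_lines = "A4", conditions = "SS")
  expect_length(small, 1)
  expect_error(
    run_panel(presets[presets$condition == "+S", ], settings,
              cell_lines = "A4", conditions = "SS"),
    "\\(A4, SS\\)")
  panel2 <- run_panel(presets, settings)
  expect_identical(panel, panel2)
})

test_that("trajectory times are strictly increasing and states stay non-negative", {
  presets <- presets_filled()
  panel <- run_panel(presets, solver_settings(t_end = 5))
  for (tr in panel) {
    expect_true(all(diff(tr$times) > 0))
    expect_true(all(tr$states >= 0))
  }
})

test_that("Euler error shrinks roughly linearly with the step size", {
  presets <- presets_filled()
  row <- presets[presets$cell_line == "CAOV3" & presets$condition == "+S", ]
  sc <- scenario_from_preset(row)
  ref <- integrate_scenario(sc, settings = solver_settings(
    t_end = 2, rtol = 1e-12, atol = 1e-12))
  ref_end <- ref$states[nrow(ref$states), ]
  err <- sapply(c(2e-3, 1e-3, 5e-4), function(dt) {
    tr <- integrate_scenario(sc, settings = solver_settings(
      t_end = 2, method = "fixed_euler", dt = dt))
    rel_err(tr$states[nrow(tr$states), ], ref_end)
  })
  expect_true(all(diff(err) < 0))
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 1.5 & ratios < 2.5))
})

test_that("adaptive and fixed-step RK4 agree on a preset scenario", {
  presets <- presets_filled()
  row <- presets[presets$cell_line == "OVMZ6" & presets$condition == "SS", ]
  sc <- scenario_from_preset(row)
  tr_a <- integrate_scenario(sc, settings = solver_settings(t_end = 5))
  tr_r <- integrate_scenario(sc, settings = solver_settings(
    t_end = 5, method = "fixed_rk4", dt = 2.5e-4))
  expect_lt(rel_err(tr_r$states[nrow(tr_r$states), ],
                    tr_a$states[nrow(tr_a$states), ]), 1e-4)
})

test_that("unbounded growth in constant-biogenesis mode raises a divergence error", {
  cs <- dynamics_constants(F_0 = 0, K_0 = 0, M_H = 0, M_D = 0,
                           alpha = 1, epsilon = 1, mu = 0,
                           biogenesis_mode = "constant", B_const = 10)
  sc <- theta_one_scenario(cs)
  expect_error(
    integrate_scenario(sc, settings = solver_settings(t_end = 10)),
    "blow-up cap")
  expect_error(
    integrate_scenario(sc, settings = solver_settings(t_end = 10)),
    "last valid time")
})

test_that("balance-mode conservation holds along every packaged trajectory", {
  presets <- presets_filled()
  panel <- run_panel(presets, solver_settings(t_end = 5))
  for (tr in panel) {
    totals <- rowSums(tr$states[, c("n_hu", "n_du", "n_hf", "n_df")])
    expect_lt(max(abs(totals - 4)) / 4, 1e-8)
  }
})
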