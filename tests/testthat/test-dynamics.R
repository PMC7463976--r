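test_that("extremum refinement is exact for a parabola and flags boundaries", {
  x <- seq(-40, 40, by = 10)
  traj <- data.frame(yp_bp = x, Up_m_per_s = 5 - 0.01 * (x - 7.3)^2,
                     converged = TRUE)
  ex <- find_extremum(traj, "Up_m_per_s", "max")
  expect_equal(ex$yp_bp, 7.3, tolerance = 1e-10)
  expect_equal(ex$value, 5, tolerance = 1e-10)
  expect_true(ex$bracketed)
  mono <- data.frame(yp_bp = x, Up_m_per_s = x, converged = TRUE)
  expect_false(find_extremum(mono, "Up_m_per_s", "max")$bracketed)
})

test_that("trajectory rows are ordered and time increases along the path", {
  tr <- fx_sweep_E(2)
  expect_true(all(diff(tr$yp_bp) > 0))
  ok <- tr$converged & is.finite(tr$t_s) & tr$Up_m_per_s > 0
  expect_true(all(diff(tr$t_s[ok]) > 0))
  expect_gt(sum(tr$converged), 0.9 * nrow(tr))
})

test_that("trajectory CSV round-trips with its metadata header", {
  tr <- fx_sweep_E(2)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_equal(back$Up_m_per_s, tr$Up_m_per_s, tolerance = 1e-9)
  expect_equal(back$I_star, tr$I_star, tolerance = 1e-9)
  meta <- attr(back, "meta")
  expect_equal(meta$E_nom_V_per_m, 2e6)
  expect_equal(meta$L_p_bp, 200)
  expect_equal(meta$I0_A, attr(tr, "I0"), tolerance = 1e-9)
})

test_that("cold restart reproduces the warm-started sweep row", {
  # asserted on the approach side: inside the pore at full speed the coupled
  # system is bistable (concentration-polarization hysteresis) and only the
  # continuation branch is comparable between runs
  tr <- fx_sweep_E(2)
  yp <- -150
  row <- tr[tr$yp_bp == yp, ]
  cold <- force_free_velocity(baseline_params(), y_p = bp_to_m(yp))
  expect_equal(cold$U_p, row$Up_m_per_s, tolerance = 0.005)
})

test_that("presets cover the field and length studies and run end to end", {
  pr <- experiment_presets()
  expect_true(all(c("fig3_E1", "fig3_E2", "fig3_E3",
                    "fig6_E1", "fig6_E2", "fig6_E3",
                    paste0("fig7_L", c(50, 100, 150, 200)),
                    paste0("fig8_L", c(50, 100, 150, 200))) %in% names(pr)))
  expect_error(preset_params("fig9_X"), "unknown preset")
  p <- preset_params("fig7_L50", "coarse")
  expect_equal(m_to_bp(p$geom$L_p), 50)
  expect_equal(p$drive$E_nom, 2e6)
  out <- tempfile()
  tr <- run_preset("fig3_E2", "coarse", out_dir = out,
                   grid_bp = c(-300, -280, -260))
  expect_true(file.exists(file.path(out, "fig3_E2_coarse.csv")))
  expect_true(file.exists(file.path(out, "run_log.jsonl")))
  expect_true(all(tr$converged))
})

test_that("field snapshots export all arrays and round-trip", {
  sol <- fx_far()$sol
  path <- tempfile(fileext = ".vtu")
  export_fields_vtu(sol, path)
  back <- read_fields_vtu(path)
  expect_setequal(names(back$data), c("phi", "c1", "c2", "c1_minus_c2", "p", "u"))
  expect_equal(back$data$phi, sol$phi, tolerance = 1e-12)
  expect_equal(back$data$c1_minus_c2, sol$conc[[1]] - sol$conc[[2]],
               tolerance = 1e-12)
  # the counter-ion excess is maximal against the particle surface
  mesh <- sol$mesh
  d <- poreflow:::.d_particle(mesh$p[, 1], mesh$p[, 2], mesh$dom)
  expect_lt(d[which.max(back$data$c1_minus_c2)], 1)
})
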