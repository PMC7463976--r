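test_that("unforced system converges immediately to the trivial state", {
  geom <- sim_geometry()
  p <- pore_params(geom = geom,
                   drive = drive_params(phi_0 = 0, geom = geom),
                   particle = particle_props(sigma_p = 0),
                   num = resolution_profile("coarse"))
  sol <- solve_steady(p, y_p = bp_to_m(-300), U_p = 0)
  expect_true(sol$converged)
  expect_lte(sum(sol$history$stage == "coupled"), 3)
  expect_lte(nrow(sol$history), 6)
  expect_lt(max(abs(sol$phi)), 1e-10)
  expect_lt(max(abs(sol$vel)), 1e-9)
  for (i in 1:2) {
    expect_equal(sol$conc[[i]], rep(10, nrow(sol$mesh$p)), tolerance = 1e-8)
  }
})

test_that("baseline solve shows a counter-ion cloud and a neutral far field", {
  sol <- fx_far()$sol
  expect_true(sol$converged)
  mesh <- sol$mesh
  d <- poreflow:::.d_particle(mesh$p[, 1], mesh$p[, 2], mesh$dom)
  dq <- sol$conc[[1]] - sol$conc[[2]]
  # cation excess against the negatively charged particle surface
  expect_gt(mean(dq[d < 2]), 1)
  # electroneutral bulk a few Debye lengths away (upper reservoir interior)
  far <- mesh$p[, 2] > 50 & mesh$p[, 1] < 40
  expect_lt(max(abs(dq[far])), 0.05 * 10)
  # no concentration undershoot beyond the tolerance
  expect_gt(min(sol$conc[[2]]), -1e-6 * 10)
})

test_that("Picard residual is monotone after the opening iterations", {
  sol <- fx_far()$sol
  r <- sol$history$residual[sol$history$stage == "coupled"]
  if (length(r) > 3) {
    expect_true(all(diff(r[-seq_len(min(3, length(r) - 1))]) <= 1e-12))
  }
  expect_lt(r[length(r)], sol$params$num$picard_tol)
})

test_that("warm starts converge in fewer iterations than cold starts", {
  p <- baseline_params()
  cold <- solve_steady(p, y_p = bp_to_m(-285), U_p = fx_far()$U_p)
  warm <- solve_steady(p, y_p = bp_to_m(-285), U_p = fx_far()$U_p,
                       state = fx_far()$sol)
  expect_lt(nrow(warm$history), nrow(cold$history))
  # and to consistent physics
  expect_equal(ionic_current(warm, 0)$I, ionic_current(cold, 0)$I,
               tolerance = 0.01)
})

test_that("boundary-layer refinement leaves the pore current consistent", {
  p1 <- baseline_params()
  I1 <- ionic_current(solve_steady(p1, y_p = bp_to_m(-300), U_p = 0), 0)$I
  p2 <- baseline_params()
  p2$num$bl_frac <- p1$num$bl_frac / 2
  I2 <- ionic_current(solve_steady(p2, y_p = bp_to_m(-300), U_p = 0), 0)$I
  expect_lt(abs(I2 - I1) / abs(I1), 0.02)
})

test_that("a failing configuration raises a convergence error with history", {
  p <- baseline_params()
  p$num$picard_max <- 2L
  err <- tryCatch(solve_steady(p, y_p = bp_to_m(-75), U_p = 0),
                  error = function(e) e)
  expect_s3_class(err, "pf_convergence_error")
  expect_true(is.data.frame(err$history))
  # and the non-stopping variant flags instead
  sol <- solve_steady(p, y_p = bp_to_m(-75), U_p = 0, stop_on_fail = FALSE)
  expect_false(sol$converged)
})
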