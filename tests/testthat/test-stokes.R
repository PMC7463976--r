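elec <- electrolyte_params()

test_that("no forcing gives the quiescent state", {
  m <- mesh_rectangle(0, 10, 0, 40, 11, 21,
                      tags = c(left = "AXIS", right = "MEMBRANE_WALL",
                               bottom = "BOTTOM_WALL", top = "TOP_WALL"),
                      mode = "planar2d")
  st <- solve_stokes(m, elec)
  expect_lt(max(abs(st$vel)), 1e-15)
  expect_lt(max(abs(st$p)), 1e-6) # Pa
})

test_that("pressure-driven channel flow reproduces the Poiseuille profile", {
  m <- mesh_rectangle(0, 10, 0, 160, 21, 81,
                      tags = c(left = "AXIS", right = "MEMBRANE_WALL",
                               bottom = "BOTTOM_WALL", top = "TOP_WALL"),
                      mode = "planar2d")
  dp <- 1e4
  st <- solve_stokes(m, elec, traction_top = dp)
  x <- m$p[, 1]
  uy_exact <- -dp * ((10e-9)^2 - (x * 1e-9)^2) / (2 * elec$mu * 160e-9)
  sel <- abs(m$p[, 2] - 80) < 20
  expect_lt(max(abs(st$vel[sel, 2] - uy_exact[sel])) / max(abs(uy_exact)), 0.01)
  # cross-channel component vanishes by symmetry
  expect_lt(max(abs(st$vel[sel, 1])), 1e-3 * max(abs(uy_exact)))
  expect_lt(st$div_residual, 1e-8)
})

test_that("electric body force vanishes in electroneutral fluid and is linear", {
  m <- mesh_rectangle(0, 10, 0, 10, 6, 6, mode = "planar2d")
  n <- nrow(m$p)
  phi <- 0.1 * m$p[, 2] / 10
  f0 <- electric_body_force(m, elec, phi, list(rep(10, n), rep(10, n)))
  expect_lt(max(abs(f0)), 1e-8)
  conc <- list(rep(12, n), rep(10, n))
  f1 <- electric_body_force(m, elec, phi, conc)
  f2 <- electric_body_force(m, elec, -phi, conc)
  expect_equal(f2, -f1, tolerance = 1e-12)
})

test_that("drag on a capped sphere matches Stokes law within wall effects", {
  geos <- sim_geometry(a = 2e-9, L_p = 4e-9, y_p = 0, W = 200e-9, H = 200e-9)
  dom <- build_domain(geos, membrane = FALSE, side_noslip = TRUE)
  m <- generate_mesh(dom, resolution_profile("coarse"), elec)
  st <- solve_stokes(m, elec, U_p = 1e-3)
  F_stokes <- -6 * pi * elec$mu * geos$a * 1e-3
  expect_lt(abs(st$force_axial / F_stokes - 1), 0.15)
  # Stokes linearity: doubled velocity doubles the drag
  st2 <- solve_stokes(m, elec, U_p = 2e-3, cache = st$cache)
  expect_equal(st2$force_axial / st$force_axial, 2, tolerance = 1e-10)
})

test_that("solution is additive in body force and particle velocity", {
  geos <- sim_geometry(a = 2e-9, L_p = 4e-9, y_p = 0, W = 100e-9, H = 100e-9)
  dom <- build_domain(geos, membrane = FALSE, side_noslip = TRUE)
  m <- generate_mesh(dom, resolution_profile("coarse"), elec)
  f <- cbind(rep(1e10, nrow(m$t)), rep(-2e10, nrow(m$t)))
  s_f <- solve_stokes(m, elec, f = f)
  s_u <- solve_stokes(m, elec, U_p = 1e-3, cache = s_f$cache)
  s_both <- solve_stokes(m, elec, f = f, U_p = 1e-3, cache = s_f$cache)
  expect_equal(s_both$vel[, 1:2], s_f$vel[, 1:2] + s_u$vel[, 1:2],
               tolerance = 1e-8)
  expect_equal(s_both$force_axial, s_f$force_axial + s_u$force_axial,
               tolerance = 1e-8)
})

test_that("open-boundary flux balances for a translating particle", {
  ff <- fx_thread()
  sol <- ff$sol
  qtop <- wall_flux(sol, "TOP_WALL")
  qbot <- wall_flux(sol, "BOTTOM_WALL")
  gross <- max(abs(qtop), abs(qbot),
               abs(sol$U_p) * pi * sol$params$geom$a^2)
  # incompressibility: the net outflow over all open boundaries vanishes
  expect_lt(abs(qtop + qbot) / gross, 0.01)
})

test_that("double-layer body force is balanced by pressure at equilibrium", {
  # equilibrium double layer in a closed-walled box with one open face:
  # no flow, hydrostatic balance of the Coulomb force, osmotic pressure
  m <- mesh_rectangle(0, 25, 0, 25, 60, 60,
                      tags = c(left = "MEMBRANE_WALL", right = "BOTTOM_WALL",
                               bottom = "MEMBRANE_WALL", top = "MEMBRANE_WALL"),
                      grade_x = 6, mode = "planar2d")
  geom <- sim_geometry()
  params <- pore_params(elec = elec, geom = geom,
                        drive = drive_params(phi_0 = 0, geom = geom),
                        particle = particle_props(sigma_p = 0),
                        num = numerics_params(picard_max = 200))
  sol <- solve_steady(params, y_p = geom$y_p, U_p = 0, mesh = m,
                      sigma_wall = -0.01)
  fe <- poreflow:::fem_setup(m)
  f <- electric_body_force(m, elec, sol$phi, sol$conc, fe = fe)
  gp <- poreflow:::field_gradient(fe, sol$p)
  # net force residual below 1% of the body-force magnitude
  res <- abs(sum((f[, 1] - gp$x / 1e-9) * fe$area)) /
    sum(abs(f[, 1]) * fe$area)
  expect_lt(res, 0.01)
  # no-flow equilibrium: residual velocity far below the electroosmotic scale
  zeta <- grahame_zeta(-0.01, elec)
  expect_lt(max(abs(sol$vel)), 0.01 * abs(elec$eps_f * zeta * 1e6 / elec$mu))
  # pressure equals the osmotic excess RT sum(c - c0) pointwise (mid-band,
  # away from the corner concentration build-up)
  osm <- elec$R_gas * elec$T_K * (sol$conc[[1]] + sol$conc[[2]] - 20)
  sel <- abs(m$p[, 2] - 12.5) < 5 & m$p[, 1] < 10
  expect_lt(max(abs(sol$p[sel] - osm[sel])) / max(abs(osm[sel])), 0.01)
})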