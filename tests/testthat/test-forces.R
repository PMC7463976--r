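elec <- electrolyte_params()

test_that("Maxwell stress integration recovers Q*E on an unscreened sphere", {
  # electrolyte so dilute that the Debye length dwarfs the domain: the net
  # force on a charged sphere in the applied field is exactly Q E
  elecL <- electrolyte_params(c0 = c(1e-5, 1e-5))
  geos <- sim_geometry(a = 1e-9, L_p = 2e-9, y_p = 0, W = 200e-9, H = 200e-9)
  drv <- drive_params(E_nom = 2e6, geom = geos)
  prt <- particle_props(sigma_p = -0.01)
  dom <- build_domain(geos, membrane = FALSE)
  msh <- generate_mesh(dom, resolution_profile("default"), elecL)
  ps <- solve_poisson(msh, elecL, drive = drv, particle = prt)
  n <- nrow(msh$p)
  sol <- structure(list(mesh = msh, fe = poreflow:::fem_setup(msh),
                        phi = ps$phi,
                        conc = list(rep(1e-5, n), rep(1e-5, n)),
                        params = list(elec = elecL, particle = prt)),
                   class = "pf_solution")
  Fexact <- -0.01 * 4 * pi * geos$a^2 * (-drv$phi_0 / (2 * geos$H + geos$h))
  Fvol <- electric_force(sol)$axial
  expect_equal(Fvol, Fexact, tolerance = 0.12)
  # the direct surface quadrature agrees only qualitatively (one-sided P1
  # gradients at a Neumann boundary): same sign, same order of magnitude
  Fsurf <- electric_force(sol, "surface")$axial
  expect_gt(Fsurf / Fexact, 0.3)
  expect_lt(Fsurf / Fexact, 1.5)
})

test_that("zero field means zero electric force", {
  sol <- fx_far()$sol
  sol0 <- sol
  sol0$phi <- rep(0, length(sol$phi))
  expect_identical(electric_force(sol0)$axial, 0)
})

test_that("an uncharged particle feels negligible electric force", {
  p0 <- pore_params(drive = drive_params(E_nom = 2e6, geom = sim_geometry()),
                    particle = particle_props(sigma_p = 0),
                    num = resolution_profile("coarse"))
  sol0 <- solve_steady(p0, y_p = bp_to_m(-75), U_p = 0)
  FE0 <- abs(electric_force(sol0)$axial)
  FE <- abs(electric_force(fx_far()$sol)$axial)
  # discretisation noise of the divergence-free stress, well below the
  # physical force scale of the charged baseline
  expect_lt(FE0, 0.05 * abs(electric_force(fx_thread()$sol)$axial))
  expect_gt(FE, 0)
})

test_that("axial electric force pulls the charged particle toward the pore", {
  FE <- electric_force(fx_far()$sol)$axial
  expect_gt(FE, 0) # negative particle, positive top potential: upward force
  # lateral force vanishes on-axis
  fb <- force_breakdown(fx_far()$sol)
  expect_lte(abs(fb$lateral), 0.01 * abs(fb$axial))
})

test_that("reaction and surface evaluations of the drag force agree", {
  geos <- sim_geometry(a = 2e-9, L_p = 4e-9, y_p = 0, W = 200e-9, H = 200e-9)
  dom <- build_domain(geos, membrane = FALSE, side_noslip = TRUE)
  msh <- generate_mesh(dom, resolution_profile("coarse"), elec)
  st <- solve_stokes(msh, elec, U_p = 1e-3)
  sol <- structure(list(mesh = msh, fe = st$cache$fe, vel = st$vel, p = st$p,
                        params = list(elec = elec),
                        force_f_axial = st$force_axial),
                   class = "pf_solution")
  Fs <- hydrodynamic_force(sol, "surface")$axial
  expect_equal(sign(Fs), sign(st$force_axial))
  expect_lt(abs(Fs / st$force_axial - 1), 0.4) # P1 surface stress is rough
})

test_that("hydrodynamic force vanishes in a quiescent fluid", {
  geos <- sim_geometry(a = 2e-9, L_p = 4e-9, y_p = 0, W = 100e-9, H = 100e-9)
  dom <- build_domain(geos, membrane = FALSE, side_noslip = TRUE)
  msh <- generate_mesh(dom, resolution_profile("coarse"), elec)
  st <- solve_stokes(msh, elec, U_p = 0)
  expect_lt(abs(st$force_axial), 1e-20)
})

test_that("force-free velocity balances the forces and responds to polarity", {
  ff <- fx_far()
  expect_gt(ff$U_p, 0)
  expect_lt(abs(ff$forces$axial), 1e-3 * abs(ff$forces$F_E$axial))
  # reversed polarity drives the particle away from the pore
  geom <- sim_geometry()
  prev <- pore_params(geom = geom,
                      drive = drive_params(E_nom = -2e6, geom = geom),
                      num = resolution_profile("coarse"))
  ffr <- force_free_velocity(prev, y_p = bp_to_m(-300))
  expect_lt(ffr$U_p, 0)
  expect_equal(abs(ffr$U_p), abs(ff$U_p), tolerance = 0.15)
})

test_that("an uncharged particle barely moves at baseline drive", {
  p0 <- pore_params(drive = drive_params(E_nom = 2e6, geom = sim_geometry()),
                    particle = particle_props(sigma_p = 0),
                    num = resolution_profile("coarse"))
  ff0 <- force_free_velocity(p0, y_p = bp_to_m(-300))
  expect_lt(abs(ff0$U_p), 1e-4) # |U| < 0.1 mm/s
})

test_that("short-particle mobility sits in the thick-double-layer window", {
  # capped sphere (L_p = 2a) in a wide anchored reservoir under uniform field
  geos <- sim_geometry(a = 1e-9, L_p = 2e-9, y_p = 0, W = 200e-9, H = 200e-9)
  ps <- pore_params(geom = geos, num = resolution_profile("coarse"),
                    drive = drive_params(E_nom = 2e6, geom = geos))
  dom <- build_domain(geos, membrane = FALSE, side_noslip = TRUE)
  m <- generate_mesh(dom, resolution_profile("coarse"), elec)
  sol <- NULL
  U <- 0
  for (outer in 1:8) {
    sol <- solve_steady(ps, y_p = 0, U_p = U, state = sol,
                        mesh = if (is.null(sol)) m else NULL)
    Ftot <- electric_force(sol)$axial + sol$force_f_axial
    st2 <- solve_stokes(sol$mesh, elec, f = sol$body_force, U_p = U + 1e-3,
                        cache = sol$caches$stokes)
    k <- (st2$force_axial - sol$force_f_axial) / 1e-3
    U_new <- U - Ftot / k
    if (abs(U_new - U) < 1e-3 * abs(U_new)) {
      U <- U_new
      break
    }
    U <- U_new
  }
  # surface potential of a sphere with kappa*a ~ 0.33 (the flat-plate value
  # would overestimate it several-fold)
  zeta <- sphere_surface_potential(-0.01, geos$a, elec)
  bounds <- smoluchowski_huckel_bounds(zeta, -2e6, elec)
  expect_gt(U, bounds[["U_huckel"]] / 2)
  expect_lt(U, bounds[["U_smol"]] * 2)
})
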