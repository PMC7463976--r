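elec <- electrolyte_params()

test_that("Laplace solve in an empty channel gives the uniform applied field", {
  geom <- sim_geometry()
  dom <- build_domain(geom, membrane = FALSE, particle = FALSE)
  m <- generate_mesh(dom, resolution_profile("coarse"), elec)
  drv <- drive_params(E_nom = 1e6, geom = geom)
  ps <- solve_poisson(m, elec, drive = drv)
  fe <- poreflow:::fem_setup(m)
  g <- poreflow:::field_gradient(fe, ps$phi)
  Ez <- -g$y / 1e-9 # V/m
  expect_equal(mean(Ez), -1e6, tolerance = 1e-6)
  expect_lt(max(abs(Ez + 1e6)) / 1e6, 1e-6)
  # linear profile: phi at mid-height is half the applied potential
  mid <- which(abs(m$p[, 2]) < 2)
  expect_equal(mean(ps$phi[mid]) / drv$phi_0, 0.5, tolerance = 0.02)
})

test_that("potential decays from a charged particle without drive", {
  sol <- fx_far()$sol
  mesh <- sol$mesh
  ps <- solve_poisson(mesh, elec, drive = NULL,
                      particle = particle_props(sigma_p = -0.01))
  d <- poreflow:::.d_particle(mesh$p[, 1], mesh$p[, 2], mesh$dom)
  expect_lt(max(ps$phi[d < 1]), 0) # negative next to the particle
  # unscreened field: magnitude decreases monotonically outward in shells
  shells <- c(mean(abs(ps$phi[d < 1])),
              mean(abs(ps$phi[d > 5 & d < 10])),
              mean(abs(ps$phi[d > 50])))
  expect_true(all(diff(shells) < 0))
  expect_lt(shells[3], 0.5 * shells[1])
})

test_that("1-D double layer follows Debye-Hueckel and Boltzmann theory", {
  sl <- fx_slab_small()
  lam <- debye_length(elec)
  # wall potential vs the (exact flat-wall) Grahame relation
  expect_equal(sl$zeta, grahame_zeta(-0.002, elec), tolerance = 0.03)
  # profile within 1% of the exponential decay
  sel <- sl$x_nm * 1e-9 < 3 * lam & sl$x_nm > 0
  prof <- debye_huckel_profile(sl$zeta, elec)
  expect_lt(max(abs(sl$phi[sel] - prof(sl$x_nm[sel] * 1e-9))) / abs(sl$zeta),
            0.01)
  # both species Boltzmann-distributed within 1%
  phiT <- thermal_voltage(elec)
  for (i in 1:2) {
    boltz <- elec$c0[i] * exp(-elec$z[i] * sl$phi[sel] / phiT)
    expect_lt(max(abs(sl$conc[[i]][sel] - boltz)) / elec$c0[i], 0.01)
  }
})

test_that("nonlinear wall potential matches the Grahame relation", {
  sl <- fx_slab_base()
  expect_equal(sl$zeta, grahame_zeta(-0.01, elec), tolerance = 0.03)
})

test_that("species flux terms are evaluated exactly for simple fields", {
  m <- mesh_rectangle(0, 10, 0, 10, 6, 6, mode = "planar2d")
  n <- nrow(m$p)
  # uniform concentration, no flow, uniform potential gradient
  phi <- 0.01 * m$p[, 2] / 10 # 10 mV over 10 nm
  conc <- list(rep(10, n), rep(10, n))
  fl <- species_flux(m, elec, phi, conc)
  gphi <- 0.01 / 10e-9
  for (i in 1:2) {
    mig <- -elec$z[i] * elec$D[i] * elec$F_const /
      (elec$R_gas * elec$T_K) * 10 * gphi
    expect_equal(fl[[i]][, 2], rep(mig, nrow(m$t)), tolerance = 1e-10)
    expect_equal(fl[[i]][, 1], rep(0, nrow(m$t)), tolerance = 1e-10)
  }
  # uniform everything: zero flux
  fl0 <- species_flux(m, elec, rep(0, n), conc)
  expect_lt(max(abs(unlist(fl0))), 1e-20)
})

test_that("fluxes cancel at Boltzmann equilibrium", {
  sl <- fx_slab_small()
  fl <- species_flux(sl$mesh, elec, sl$phi, sl$conc)
  fe <- poreflow:::fem_setup(sl$mesh)
  gphi <- poreflow:::field_gradient(fe, sl$phi)
  drift <- abs(elec$z[1] * elec$D[1] * elec$F_const / (elec$R_gas * elec$T_K) *
                 poreflow:::field_centroid(fe, sl$conc[[1]]) * gphi$x / 1e-9)
  sel <- drift > 0.05 * max(drift) # inside the double layer
  expect_lt(max(abs(fl[[1]][sel, 1])) / max(drift), 1e-2)
})

test_that("discrete species transport is globally conservative", {
  sl <- fx_slab_small()
  mesh <- sl$mesh
  fe <- poreflow:::fem_setup(mesh)
  sc <- poreflow:::scales_of(elec)
  gphi <- poreflow:::field_gradient(fe, sl$phi / sc$phi_T)
  for (i in 1:2) {
    A <- poreflow:::assemble_advection_diffusion(
      fe, -elec$z[i] * gphi$x, -elec$z[i] * gphi$y)
    res <- as.numeric(A %*% (sl$conc[[i]] / sc$C0))
    # the residual at Dirichlet nodes is the boundary flux; partition of
    # unity makes the total vanish identically
    expect_lt(abs(sum(res)), 1e-8 * max(sum(abs(res)), 1e-300))
  }
})

test_that("reversing all charges mirrors the solution when D1 = D2", {
  elec_eq <- electrolyte_params(D = c(2e-9, 2e-9))
  a <- dl_slab(-0.004, elec_eq, nx = 60)
  b <- dl_slab(+0.004, elec_eq, nx = 60)
  expect_equal(b$phi, -a$phi, tolerance = 1e-8)
  expect_equal(b$conc[[1]], a$conc[[2]], tolerance = 1e-8)
  expect_equal(b$conc[[2]], a$conc[[1]], tolerance = 1e-8)
})

test_that("quiescent uniform state is a fixed point of the transport solve", {
  m <- mesh_rectangle(0, 10, 0, 20, 6, 11, mode = "planar2d")
  n <- nrow(m$p)
  nps <- solve_nernst_planck(m, elec, phi = rep(0.005, n))
  for (i in 1:2) expect_equal(nps$conc[[i]], rep(elec$c0[i], n), tolerance = 1e-10)
})
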