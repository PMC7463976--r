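test_that("baseline parameter set is valid and carries the study values", {
  p <- pore_params()
  expect_s3_class(p, "pore_params")
  expect_equal(p$geom$W, 100e-9)
  expect_equal(p$geom$H, 200e-9)
  expect_equal(p$geom$h, 5e-9)
  expect_equal(p$geom$b, 5e-9)
  expect_equal(p$geom$a, 1e-9)
  expect_equal(p$elec$c0, c(10, 10))
  expect_equal(p$particle$sigma_p, -0.01)
  expect_equal(p$elec$T_K, 300)
})

test_that("geometry invariants are enforced", {
  expect_error(sim_geometry(b = 1.5e-9, a = 1e-9), "does not fit pore")
  expect_error(sim_geometry(L_p = 500e-9, H = 200e-9), "reservoir")
  expect_error(sim_geometry(L_p = 1e-9, a = 1e-9), "minimum particle")
  expect_error(electrolyte_params(c0 = c(10, 5)), "electroneutrality")
  expect_error(electrolyte_params(T_K = -1), "positive")
})

test_that("nominal field and applied potential are mutually consistent", {
  geom <- sim_geometry()
  d <- drive_params(E_nom = 2e6, geom = geom)
  expect_equal(d$phi_0, 2e6 * (2 * 200e-9 + 5e-9)) # 0.81 V
  expect_equal(d$phi_0, 0.81)
  d2 <- drive_params(phi_0 = -0.81, geom = geom)
  expect_equal(d2$E_nom, -2e6)
  expect_error(drive_params(geom = geom), "one of")
})

test_that("base-pair unit conversions are exact inverses", {
  x <- c(-300, -75, 0, 117, 300.5)
  expect_identical(m_to_bp(bp_to_m(x)), x)
  expect_equal(bp_to_m(1), 0.34e-9)
})

test_that("Debye length matches the closed form", {
  elec <- electrolyte_params()
  lam <- sqrt(elec$eps_f * elec$R_gas * elec$T_K /
                (elec$F_const^2 * sum(elec$z^2 * elec$c0)))
  expect_equal(debye_length(elec), lam, tolerance = 1e-12)
  expect_equal(debye_length(elec) * 1e9, 3.08, tolerance = 1e-3)
  # inverse-square-root concentration scaling
  elec4 <- electrolyte_params(c0 = c(40, 40))
  expect_equal(debye_length(elec4), debye_length(elec) / 2, tolerance = 1e-12)
  # kappa*a for the baseline particle
  expect_equal(1e-9 / debye_length(elec), 0.325, tolerance = 1e-2)
})

test_that("bulk conductivity matches the Nernst-Einstein closed form", {
  elec <- electrolyte_params()
  sig <- elec$F_const^2 / (elec$R_gas * elec$T_K) *
    sum(elec$z^2 * elec$D * elec$c0)
  expect_equal(bulk_conductivity(elec), sig, tolerance = 1e-12)
  expect_equal(bulk_conductivity(elec), 0.149, tolerance = 5e-3)
  # linear in the diffusivities and in the concentration
  elec2 <- electrolyte_params(D = 2 * c(1.95e-9, 2.03e-9))
  expect_equal(bulk_conductivity(elec2), 2 * sig, tolerance = 1e-12)
  elec_half <- electrolyte_params(c0 = c(5, 5))
  expect_equal(bulk_conductivity(elec_half), sig / 2, tolerance = 1e-12)
})

test_that("parameter serialization round-trips field-for-field", {
  p <- pore_params(drive = drive_params(E_nom = 3e6, geom = sim_geometry()),
                   num = resolution_profile("coarse"))
  path <- tempfile(fileext = ".yaml")
  write_parameters(p, path)
  q <- load_parameters(path)
  for (blk in c("elec", "geom", "drive", "particle")) {
    expect_equal(unclass(q[[blk]]), unclass(p[[blk]]), tolerance = 1e-12,
                 info = blk)
  }
  expect_equal(q$num$bl_frac, p$num$bl_frac)
  expect_equal(q$num$grid_bp, p$num$grid_bp)
  expect_identical(q$mode, p$mode)
})

test_that("configuration errors name the offending key or invariant", {
  expect_error(load_parameters("b_nm: 1.5\na_nm: 1"), "fit pore")
  # convenience keys: nm and bp suffixes and field in MV/m
  p <- load_parameters("L_p_bp: 100\nE_nom_MV_per_m: 3\ny_p_bp: -150")
  expect_equal(m_to_bp(p$geom$L_p), 100)
  expect_equal(p$drive$E_nom, 3e6)
  expect_equal(m_to_bp(p$geom$y_p), -150)
})
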