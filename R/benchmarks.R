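# Closed-form electrokinetic oracles and the verification benchmarks built
# on them. Every oracle is a pure function of its inputs; the run_benchmarks()
# table compares the numerical solvers against them on small fixtures that
# are generated in code.

#' Debye-Hueckel potential profile at a planar wall
#'
#' `psi(x) = zeta exp(-x / lambda_D)`, valid for |zeta| below about 25 mV.
#'
#' @param zeta wall (surface) potential (V)
#' @param elec `electrolyte_params`
#' @return function of distance x (m)
#' @export
debye_huckel_profile <- function(zeta, elec) {
  lam <- debye_length(elec)
  function(x) zeta * exp(-x / lam)
}

#' Grahame relation between surface charge and surface potential
#'
#' For a symmetric 1:1 electrolyte,
#' `sigma = sqrt(8 eps RT C0) sinh(F zeta / (2RT))`.
#'
#' @param sigma surface charge density (C/m2)
#' @param elec `electrolyte_params`
#' @return surface potential (V)
#' @export
grahame_zeta <- function(sigma, elec) {
  2 * thermal_voltage(elec) *
    asinh(sigma / sqrt(8 * elec$eps_f * elec$R_gas * elec$T_K * elec$c0[1]))
}

#' @rdname grahame_zeta
#' @param zeta surface potential (V)
#' @export
grahame_sigma <- function(zeta, elec) {
  sqrt(8 * elec$eps_f * elec$R_gas * elec$T_K * elec$c0[1]) *
    sinh(zeta / (2 * thermal_voltage(elec)))
}

#' Surface potential of a small sphere in the thick-double-layer regime
#'
#' Linearised relation `zeta = sigma a / (eps (1 + kappa a))`; the flat-plate
#' Grahame value overestimates the potential of a particle whose radius is
#' below the Debye length.
#'
#' @param sigma surface charge density (C/m2)
#' @param a sphere radius (m)
#' @param elec `electrolyte_params`
#' @return surface potential (V)
#' @export
sphere_surface_potential <- function(sigma, a, elec) {
  ka <- a / debye_length(elec)
  sigma * a / (elec$eps_f * (1 + ka))
}

#' Hueckel and Smoluchowski electrophoretic velocity bounds
#'
#' Thick- and thin-double-layer limits `2 eps zeta E / (3 mu)` and
#' `eps zeta E / mu`; any reasonable mobility at intermediate kappa*a lies
#' between them.
#'
#' @param zeta surface potential (V)
#' @param E applied field (V/m)
#' @param elec `electrolyte_params`
#' @return named vector `c(U_huckel, U_smol)` (m/s)
#' @export
smoluchowski_huckel_bounds <- function(zeta, E, elec) {
  c(U_huckel = 2 * elec$eps_f * zeta * E / (3 * elec$mu),
    U_smol = elec$eps_f * zeta * E / elec$mu)
}

#' Ohmic series-resistance estimate of the pore current
#'
#' Pore resistance `h / (sigma pi (b/2)^2)` plus one Hall access resistance
#' `1/(2 sigma b)` per side; `I = phi_0 / R_total`. A thin-double-layer,
#' neutral-channel estimate used as an order-of-magnitude gate on the base
#' current.
#'
#' @param params `pore_params`
#' @return list with `I` (A), `R_total`, `R_pore`, `R_access` (Ohm)
#' @export
ohmic_pore_current <- function(params) {
  sig <- bulk_conductivity(params$elec)
  b <- params$geom$b
  R_pore <- params$geom$h / (sig * pi * (b / 2)^2)
  R_access <- 1 / (2 * sig * b)
  R_total <- R_pore + 2 * R_access
  list(I = params$drive$phi_0 / R_total, R_total = R_total,
       R_pore = R_pore, R_access = R_access)
}

## ---------------------------------------------------------------------------
## Numerical benchmark fixtures (meshes built in code)

#' One-dimensional double-layer slab solved with the coupled solver
#'
#' A planar slab with a charged no-slip wall on the left and bulk conditions
#' on the right, the standard equilibrium fixture: the converged potential
#' must follow the Grahame/Debye-Hueckel theory and the ion densities the
#' Boltzmann distribution.
#'
#' @param sigma wall charge density (C/m2)
#' @param elec `electrolyte_params`
#' @param nx,Lx_nm resolution and slab depth (nm)
#' @return list: `mesh`, `x_nm`, `phi` (V), `conc`, `zeta` (V), `sol`
#' @export
dl_slab <- function(sigma, elec = electrolyte_params(), nx = 120, Lx_nm = 25) {
  mesh <- mesh_rectangle(0, Lx_nm, 0, 2, nx, 3,
                         tags = c(left = "MEMBRANE_WALL", right = "BOTTOM_WALL",
                                  bottom = "SIDE_BOUNDARY", top = "SIDE_BOUNDARY"),
                         grade_x = 12, mode = "planar2d")
  geom <- sim_geometry() # placeholder; the slab mesh overrides the domain
  params <- pore_params(elec = elec, geom = geom,
                        drive = drive_params(phi_0 = 0, geom = geom),
                        particle = particle_props(sigma_p = 0, eps_p = elec$eps_f),
                        num = numerics_params(picard_max = 200))
  sol <- solve_steady(params, y_p = geom$y_p, U_p = 0, mesh = mesh,
                      sigma_wall = sigma)
  wall <- which(mesh$p[, 1] < 1e-9)
  list(mesh = mesh, x_nm = mesh$p[, 1], phi = sol$phi, conc = sol$conc,
       zeta = mean(sol$phi[wall]), sol = sol)
}

#' Electroosmotic slit flow solved with the coupled solver
#'
#' Half of a parallel-plate channel with charged no-slip walls and an axial
#' field; outside the double layer the velocity must approach the
#' Helmholtz-Smoluchowski slip speed.
#'
#' @param sigma wall charge (C/m2)
#' @param E axial field magnitude (V/m)
#' @param C0 bulk concentration (mol/m3) (chosen so the slit is many Debye
#'   lengths wide)
#' @param half_width_nm,length_nm channel dimensions (nm)
#' @return list: `u_mid` (m/s, axial velocity on the channel axis), `u_hs`
#'   (Smoluchowski slip speed with the Grahame zeta), `sol`
#' @export
eo_slit <- function(sigma = -0.005, E = 1e6, C0 = 100,
                    half_width_nm = 10, length_nm = 160) {
  elec <- electrolyte_params(c0 = c(C0, C0))
  # charged no-slip wall on the left, channel midplane (symmetry) on the
  # right, open ends top/bottom
  mesh <- mesh_rectangle(0, half_width_nm, 0, length_nm, 26, 31,
                         tags = c(left = "MEMBRANE_WALL", right = "AXIS",
                                  bottom = "BOTTOM_WALL", top = "TOP_WALL"),
                         grade_x = 8, mode = "planar2d")
  geom <- sim_geometry()
  params <- pore_params(elec = elec, geom = geom,
                        drive = drive_params(phi_0 = 0, geom = geom),
                        particle = particle_props(sigma_p = 0, eps_p = elec$eps_f),
                        num = numerics_params(picard_max = 200))
  # equilibrium double layer (no axial drive); in a uniform channel the
  # tangential field decouples from the transverse EDL structure, so the
  # electroosmotic flow is driven exactly by f_z = rho_e(x) * E
  sol <- solve_steady(params, y_p = geom$y_p, U_p = 0, mesh = mesh,
                      sigma_wall = sigma)
  fe <- sol$fe
  rho <- (field_centroid(fe, sol$conc[[1]]) -
            field_centroid(fe, sol$conc[[2]])) * elec$F_const
  f <- cbind(0, rho * E)
  st <- solve_stokes(mesh, elec, f = f, cache = sol$caches$stokes)
  mid <- which(mesh$p[, 1] > half_width_nm - 1e-6 &
                 abs(mesh$p[, 2] - length_nm / 2) < length_nm / 6)
  zeta <- grahame_zeta(sigma, elec)
  u_hs <- -elec$eps_f * zeta * E / elec$mu
  list(u_mid = mean(st$vel[mid, 2]), u_hs = u_hs, sol = sol, zeta = zeta)
}

#' Run the closed-form benchmark table
#'
#' Compares the numerical solvers against the analytic oracles on fixtures
#' generated in code and returns a pass/fail table.
#'
#' @param quick skip the slower flow benchmarks
#' @return data frame: name, computed, oracle, rel_error, tolerance, pass
#' @export
run_benchmarks <- function(quick = FALSE) {
  elec <- electrolyte_params()
  rows <- list()
  add <- function(name, computed, oracle, tol) {
    # when the oracle is an exact zero the computed value is itself the error
    rel <- if (oracle == 0) abs(computed) else abs(computed - oracle) / abs(oracle)
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, computed = computed, oracle = oracle,
      rel_error = rel, tolerance = tol)
  }
  add("debye_length_nm", debye_length(elec) * 1e9,
      sqrt(elec$eps_f * elec$R_gas * elec$T_K / (elec$F_const^2 * 20)) * 1e9, 1e-12)
  add("bulk_conductivity_S_per_m", bulk_conductivity(elec),
      elec$F_const^2 * 10 * (1.95e-9 + 2.03e-9) / (elec$R_gas * elec$T_K), 1e-12)

  # 1-D double layer: wall potential vs Grahame, profile vs Debye-Hueckel
  sl <- dl_slab(-0.002, elec)
  add("slab_zeta_vs_grahame", sl$zeta, grahame_zeta(-0.002, elec), 0.03)
  lam <- debye_length(elec)
  sel <- sl$x_nm * 1e-9 < 3 * lam & sl$x_nm > 0
  prof <- debye_huckel_profile(sl$zeta, elec)
  add("slab_profile_vs_debye_huckel",
      max(abs(sl$phi[sel] - prof(sl$x_nm[sel] * 1e-9))) / abs(sl$zeta), 0, 0.01)
  boltz <- elec$c0[1] * exp(-sl$phi[sel] / thermal_voltage(elec))
  add("slab_boltzmann_c1",
      max(abs(sl$conc[[1]][sel] - boltz)) / elec$c0[1], 0, 0.01)

  if (!quick) {
    # Poiseuille channel (planar, pressure-driven)
    # the open traction ends perturb the profile within ~2 channel widths;
    # a long channel isolates the fully developed mid-section
    mshP <- mesh_rectangle(0, 10, 0, 160, 21, 81,
                           tags = c(left = "AXIS", right = "MEMBRANE_WALL",
                                    bottom = "BOTTOM_WALL", top = "TOP_WALL"),
                           mode = "planar2d")
    dp <- 1e4
    st <- solve_stokes(mshP, elec, traction_top = dp)
    x <- mshP$p[, 1]
    uy_exact <- -dp * ((10e-9)^2 - (x * 1e-9)^2) / (2 * elec$mu * 160e-9)
    selm <- abs(mshP$p[, 2] - 80) < 20
    add("poiseuille_profile",
        max(abs(st$vel[selm, 2] - uy_exact[selm])) / max(abs(uy_exact)), 0, 0.01)

    eo <- eo_slit()
    add("helmholtz_smoluchowski_slip", eo$u_mid, eo$u_hs, 0.05)
  }
  out <- do.call(rbind, rows)
  out$pass <- out$rel_error <= out$tolerance
  out
}
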