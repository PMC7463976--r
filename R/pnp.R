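# Poisson and steady Nernst-Planck solvers.
#
# Physics (SI form):
#   -eps_f lap(phi) = F (z1 c1 + z2 c2)                     (potential)
#   div(N_i) = 0,  N_i = u c_i - D_i grad c_i - z_i D_i F/(RT) c_i grad phi
# with phi = phi_0 / 0 and c_i = c0 on the top/bottom open walls, surface
# charge -n.grad(phi) = sigma_p/eps_f on the particle, insulation elsewhere,
# and a purely convective normal ion flux on the (moving) particle surface.

#' Solve the Poisson equation on a mesh
#'
#' @param mesh `pf_mesh`
#' @param elec `electrolyte_params`
#' @param drive `drive_params` or `NULL` (grounded top and bottom)
#' @param particle `particle_props` or `NULL` (uncharged)
#' @param conc list of nodal concentration vectors (mol/m3), one per species,
#'   or `NULL` for a charge-free solve
#' @param sigma_wall optional surface charge density (C/m2) on
#'   `MEMBRANE_WALL` edges (used by electroosmotic benchmarks)
#' @param phi_prev previous nodal potential iterate (V). When supplied
#'   together with `conc`, the space charge is linearised about the previous
#'   iterate (Gummel iteration): the Boltzmann response of each species adds a
#'   screening term to the operator, which keeps the electrostatic fixed point
#'   stable at strong surface charge where a bare source-term update diverges.
#' @param cache factorisation cache from a previous call on the same mesh
#' @return list with `phi` (V, nodal), `cache`
#' @export
solve_poisson <- function(mesh, elec, drive = NULL, particle = NULL,
                          conc = NULL, sigma_wall = 0, phi_prev = NULL,
                          cache = NULL) {
  sc <- scales_of(elec)
  if (is.null(cache)) cache <- list(fe = fem_setup(mesh))
  fe <- cache$fe
  if (is.null(cache$K)) cache$K <- assemble_stiffness(fe)
  if (is.null(cache$M)) cache$M <- assemble_mass(fe)
  rhs <- numeric(fe$n)
  K <- cache$K
  gummel <- !is.null(conc) && !is.null(phi_prev)
  if (!is.null(conc)) {
    rho <- numeric(fe$n) # scaled charge density sum z c~
    for (i in seq_along(conc)) rho <- rho + elec$z[i] * conc[[i]] / sc$C0
    rhs <- rhs + sc$beta * as.numeric(cache$M %*% rho)
  }
  if (gummel) {
    scr <- numeric(fe$m) # sum z^2 c~ per element
    for (i in seq_along(conc)) {
      scr <- scr + elec$z[i]^2 * field_centroid(fe, conc[[i]] / sc$C0)
    }
    # transient concentration undershoots must not break positive-definiteness
    Mg <- assemble_mass(fe, coef = sc$beta * pmax(scr, 0))
    K <- K + Mg
    rhs <- rhs + as.numeric(Mg %*% (phi_prev / sc$phi_T))
  }
  if (!is.null(particle) && particle$sigma_p != 0) {
    sig <- particle$sigma_p * sc$L0 / (elec$eps_f * sc$phi_T)
    rhs <- rhs + edge_load(mesh, tagged_edges(mesh, "PARTICLE_SURFACE"), sig)
  }
  if (sigma_wall != 0) {
    sigw <- sigma_wall * sc$L0 / (elec$eps_f * sc$phi_T)
    rhs <- rhs + edge_load(mesh, tagged_edges(mesh, "MEMBRANE_WALL"), sigw)
  }
  top <- nodes_on_tag(mesh, "TOP_WALL")
  bot <- nodes_on_tag(mesh, "BOTTOM_WALL")
  if (length(top) + length(bot) == 0) {
    stop("solver error: no Dirichlet wall present, Poisson system is singular")
  }
  phi_top <- if (is.null(drive)) 0 else drive$phi_0 / sc$phi_T
  fix <- c(top, bot)
  val <- c(rep(phi_top, length(top)), rep(0, length(bot)))
  if (gummel) {
    # operator changes with the concentration iterate: no factor reuse
    sol <- fem_solve(K, rhs, fix, val, symmetric = TRUE)
  } else {
    sol <- fem_solve(K, rhs, fix, val, cache = cache$dir, symmetric = TRUE)
    cache$dir <- sol$cache
  }
  list(phi = sol$x * sc$phi_T, cache = cache)
}

#' Solve the steady Nernst-Planck equations for all species
#'
#' The potential and flow fields are frozen; each species then satisfies a
#' linear steady advection-diffusion equation in which the drift combines
#' electromigration and convection. Bulk concentrations are imposed on the
#' open top/bottom walls; the particle surface carries the convective-flux
#' condition `n.N_i = n.(u c_i)`; all other walls are impermeable.
#'
#' @param mesh `pf_mesh`
#' @param elec `electrolyte_params`
#' @param phi nodal potential (V)
#' @param vel nodal velocity (m/s), an n x 2 matrix, or `NULL` for a
#'   quiescent fluid; an optional `attr(vel, "bubble")` (m x 2) carries the
#'   element bubble component of a MINI-element flow solution
#' @param U_p particle translation velocity (m/s) entering the convective
#'   surface-flux condition
#' @param check error on concentrations below `-1e-6 c0` (set `FALSE` inside
#'   outer coupling iterations where transients are expected)
#' @param supg streamline stabilisation of the drift term (default on)
#' @param cache assembly cache
#' @return list with `conc` (list of nodal mol/m3 per species), `cache`
#' @export
solve_nernst_planck <- function(mesh, elec, phi, vel = NULL, U_p = 0,
                                check = TRUE, supg = TRUE, cache = NULL) {
  sc <- scales_of(elec)
  if (is.null(cache)) cache <- list(fe = fem_setup(mesh))
  fe <- cache$fe
  gphi <- field_gradient(fe, phi / sc$phi_T)
  ue <- .element_velocity(fe, vel) # scaled, per element
  top <- nodes_on_tag(mesh, "TOP_WALL")
  bot <- nodes_on_tag(mesh, "BOTTOM_WALL")
  pedges <- tagged_edges(mesh, "PARTICLE_SURFACE")
  en <- if (nrow(pedges) > 0) edge_normals(mesh, pedges) else NULL
  conc <- vector("list", length(elec$z))
  for (i in seq_along(elec$z)) {
    wx <- sc$Pe[i] * ue$x / sc$U0 - elec$z[i] * gphi$x
    wy <- sc$Pe[i] * ue$y / sc$U0 - elec$z[i] * gphi$y
    A <- assemble_advection_diffusion(fe, wx, wy, supg = supg)
    if (!is.null(en) && U_p != 0) {
      # n.(u c) with u = (0, U_p) on the particle surface
      g <- sc$Pe[i] * (U_p / sc$U0) * en$ny
      A <- A + edge_mass(mesh, pedges, g)
    }
    fix <- c(top, bot)
    val <- rep(elec$c0[i] / sc$C0, length(fix))
    sol <- fem_solve(A, numeric(fe$n), fix, val)
    ci <- sol$x * sc$C0
    if (check && min(ci) < -1e-6 * sc$C0) {
      stop(sprintf(paste0("resolution error: species %d concentration ",
                          "reaches %.3g mol/m3; refine the boundary layer"),
                   i, min(ci)))
    }
    conc[[i]] <- ci
  }
  list(conc = conc, cache = cache)
}

# element-wise mean of a MINI velocity field, in the units of `vel` (m/s);
# the cubic bubble contributes 9/20 of its coefficient to the element mean
.element_velocity <- function(fe, vel) {
  if (is.null(vel)) return(list(x = numeric(fe$m), y = numeric(fe$m)))
  ub <- attr(vel, "bubble")
  ux <- field_centroid(fe, vel[, 1])
  uy <- field_centroid(fe, vel[, 2])
  if (!is.null(ub)) {
    ux <- ux + 0.45 * ub[, 1]
    uy <- uy + 0.45 * ub[, 2]
  }
  list(x = ux, y = uy)
}

#' Species flux vectors per element
#'
#' Evaluates `N_i = u c_i - D_i grad c_i - z_i D_i F/(RT) c_i grad phi`
#' elementwise (SI units, mol/(m2 s)).
#'
#' @inheritParams solve_nernst_planck
#' @param conc list of nodal concentrations (mol/m3)
#' @param fe optional precomputed [fem_setup()]
#' @return list per species of m x 2 matrices
#' @export
species_flux <- function(mesh, elec, phi, conc, vel = NULL, fe = NULL) {
  if (is.null(fe)) fe <- fem_setup(mesh)
  gphi <- field_gradient(fe, phi) # V/nm
  nm <- 1e-9
  out <- vector("list", length(conc))
  ue <- .element_velocity(fe, vel) # m/s
  for (i in seq_along(conc)) {
    ci <- field_centroid(fe, conc[[i]])
    gci <- field_gradient(fe, conc[[i]]) # mol/m3 per nm
    mig <- elec$z[i] * elec$D[i] * elec$F_const /
      (elec$R_gas * elec$T_K) * ci
    Nx <- ue$x * ci - elec$D[i] * gci$x / nm - mig * gphi$x / nm
    Ny <- ue$y * ci - elec$D[i] * gci$y / nm - mig * gphi$y / nm
    out[[i]] <- cbind(Nx, Ny)
  }
  out
}
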