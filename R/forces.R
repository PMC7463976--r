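# Forces on the particle by stress integration, and the force-free
# (quasi-static) translocation velocity.
#
# The electric force is the Maxwell stress eps_p [EE - 1/2 (E.E) I]
# integrated over the particle surface; the hydrodynamic force is the total
# fluid stress [-p I + mu (grad u + grad u^T)]. Two evaluation routes are
# provided for each: a superconvergent one used by the dynamics (volume form
# of the Maxwell stress with a nodal indicator; consistent reaction force for
# the fluid stress) and a direct surface quadrature used as a cross-check.

# map each boundary edge to the triangle containing it
.edge_element <- function(mesh) {
  tri <- mesh$t
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(ek(tri[, 1], tri[, 2]), ek(tri[, 2], tri[, 3]), ek(tri[, 3], tri[, 1]))
  el <- rep(seq_len(nrow(tri)), 3)
  idx <- match(ek(mesh$be[, 1], mesh$be[, 2]), keys)
  el[idx]
}

#' Electric (Maxwell stress) force on the particle
#'
#' @param sol `pf_solution`
#' @param method `"volume"` (superconvergent indicator form, default) or
#'   `"surface"` (direct quadrature over boundary edges)
#' @return list with `axial` and `lateral` force components (N)
#' @export
electric_force <- function(sol, method = c("volume", "surface")) {
  method <- match.arg(method)
  mesh <- sol$mesh
  elec <- sol$params$elec
  sc <- scales_of(elec)
  fe <- sol$fe
  epsr <- sol$params$particle$eps_p / elec$eps_f
  g <- field_gradient(fe, sol$phi / sc$phi_T) # scaled potential gradient per nm
  Ex <- -g$x
  Ey <- -g$y
  Trr <- Ex * Ex - 0.5 * (Ex^2 + Ey^2)
  Tzz <- Ey * Ey - 0.5 * (Ex^2 + Ey^2)
  Trz <- Ex * Ey
  geomfac <- if (fe$axi) 2 * pi else 1
  if (method == "surface") {
    pedges <- tagged_edges(mesh, "PARTICLE_SURFACE")
    eid <- .edge_element(mesh)[mesh$be_tag == PF_TAGS[["PARTICLE_SURFACE"]]]
    en <- edge_normals(mesh, pedges)
    # edge normals point out of the fluid = into the particle; the particle
    # outward normal is the negative
    w <- if (fe$axi) en$mx else 1
    Fz <- -sum((Trz[eid] * en$nx + Tzz[eid] * en$ny) * en$len * w)
    Fx <- -sum((Trr[eid] * en$nx + Trz[eid] * en$ny) * en$len * w)
  } else {
    chi <- as.numeric(seq_len(fe$n) %in% nodes_on_tag(mesh, "PARTICLE_SURFACE"))
    gchi <- field_gradient(fe, chi)
    rho <- numeric(fe$n)
    for (i in seq_along(sol$conc)) {
      rho <- rho + elec$z[i] * sol$conc[[i]] / sc$C0
    }
    rho <- sc$beta * rho # scaled space charge
    wA <- rowSums(fe$w3 * .QR3$w[col(fe$w3)]) * fe$area
    # int chi rho E with P1 chi, rho at quadrature points
    acc_z <- acc_x <- numeric(fe$m)
    for (q in 1:3) {
      chiq <- rowSums(matrix(chi[fe$t], ncol = 3) * rep(.QR3$bary[q, ], each = fe$m))
      rhoq <- rowSums(matrix(rho[fe$t], ncol = 3) * rep(.QR3$bary[q, ], each = fe$m))
      acc_z <- acc_z + .QR3$w[q] * fe$w3[, q] * chiq * rhoq
      acc_x <- acc_x + .QR3$w[q] * fe$w3[, q] * chiq * rhoq
    }
    Fz <- -sum((Trz * gchi$x + Tzz * gchi$y) * wA) - sum(acc_z * fe$area * Ey)
    Fx <- -sum((Trr * gchi$x + Trz * gchi$y) * wA) - sum(acc_x * fe$area * Ex)
  }
  axial <- Fz * geomfac * sc$F0 * epsr
  lateral <- if (fe$axi) 0 else Fx * geomfac * sc$F0 * epsr
  list(axial = axial, lateral = lateral, method = method)
}

#' Hydrodynamic force on the particle
#'
#' @param sol `pf_solution`
#' @param method `"reaction"` (consistent reaction of the Stokes system,
#'   default) or `"surface"` (direct stress quadrature over boundary edges)
#' @return list with `axial` and `lateral` components (N)
#' @export
hydrodynamic_force <- function(sol, method = c("reaction", "surface")) {
  method <- match.arg(method)
  mesh <- sol$mesh
  elec <- sol$params$elec
  sc <- scales_of(elec)
  fe <- sol$fe
  if (method == "reaction") {
    return(list(axial = sol$force_f_axial, lateral = 0, method = method))
  }
  geomfac <- if (fe$axi) 2 * pi else 1
  pedges <- tagged_edges(mesh, "PARTICLE_SURFACE")
  eid <- .edge_element(mesh)[mesh$be_tag == PF_TAGS[["PARTICLE_SURFACE"]]]
  en <- edge_normals(mesh, pedges)
  ur <- sol$vel[, 1] / sc$U0
  uz <- sol$vel[, 2] / sc$U0
  gur <- field_gradient(fe, ur)
  guz <- field_gradient(fe, uz)
  # bubble gradient at the edge midpoint (the bubble vanishes on the edge but
  # its normal derivative does not)
  ub <- attr(sol$vel, "bubble")
  if (!is.null(ub)) {
    lam <- .edge_midpoint_bary(mesh, pedges, eid)
    bg <- 27 * (lam[, 2] * lam[, 3] * cbind(fe$gx[eid, 1], fe$gy[eid, 1]) +
                  lam[, 1] * lam[, 3] * cbind(fe$gx[eid, 2], fe$gy[eid, 2]) +
                  lam[, 1] * lam[, 2] * cbind(fe$gx[eid, 3], fe$gy[eid, 3]))
    gur_x <- gur$x[eid] + bg[, 1] * ub[eid, 1] / sc$U0
    gur_y <- gur$y[eid] + bg[, 2] * ub[eid, 1] / sc$U0
    guz_x <- guz$x[eid] + bg[, 1] * ub[eid, 2] / sc$U0
    guz_y <- guz$y[eid] + bg[, 2] * ub[eid, 2] / sc$U0
  } else {
    gur_x <- gur$x[eid]; gur_y <- gur$y[eid]
    guz_x <- guz$x[eid]; guz_y <- guz$y[eid]
  }
  pmid <- (sol$p[pedges[, 1]] + sol$p[pedges[, 2]]) / 2 / sc$P0
  s_zz <- -pmid + 2 * guz_y
  s_rz <- guz_x + gur_y
  s_rr <- -pmid + 2 * gur_x
  w <- if (fe$axi) en$mx else 1
  Fz <- -sum((s_rz * en$nx + s_zz * en$ny) * en$len * w)
  Fx <- -sum((s_rr * en$nx + s_rz * en$ny) * en$len * w)
  list(axial = Fz * geomfac * sc$F0,
       lateral = if (fe$axi) 0 else Fx * geomfac * sc$F0,
       method = method)
}

# barycentric coordinates of boundary-edge midpoints in their elements
.edge_midpoint_bary <- function(mesh, edges, eid) {
  out <- matrix(0, nrow(edges), 3)
  for (k in seq_len(nrow(edges))) {
    tv <- mesh$t[eid[k], ]
    out[k, match(edges[k, 1], tv)] <- 0.5
    out[k, match(edges[k, 2], tv)] <- 0.5
  }
  out
}

#' Full force breakdown on the particle
#'
#' @param sol `pf_solution`
#' @return list with electric, hydrodynamic and total axial/lateral forces (N)
#' @export
force_breakdown <- function(sol) {
  FE <- electric_force(sol)
  Ff <- hydrodynamic_force(sol)
  list(F_E = FE, F_f = Ff,
       axial = FE$axial + Ff$axial,
       lateral = FE$lateral + Ff$lateral)
}

#' Force-free (quasi-static) translocation velocity at one position
#'
#' Finds the particle velocity at which the net axial force (Maxwell stress
#' plus fluid stress) vanishes. The axial fluid force is affine in the
#' prescribed velocity at frozen charge fields (Stokes linearity), so each
#' outer step solves the coupled system, probes the drag slope with one
#' additional Stokes back-solve on the cached factorisation, and jumps to the
#' predicted zero; the loop re-couples until the velocity is stationary to
#' `num$ff_tol` and the net force is below `ff_tol * |F_E|`.
#'
#' @param params `pore_params`
#' @param y_p particle position (m)
#' @param state optional warm-start `pf_solution` (typically the previous
#'   sweep position)
#' @param max_outer maximum outer iterations
#' @return list: `U_p` (m/s), `sol` (`pf_solution`), `forces`, `outer_iters`
#' @export
force_free_velocity <- function(params, y_p = NULL, state = NULL,
                                max_outer = 10) {
  if (is.null(y_p)) y_p <- params$geom$y_p
  U <- if (!is.null(state) && !is.null(state$U_p)) state$U_p else 0
  tol <- params$num$ff_tol
  sol <- NULL
  for (outer in seq_len(max_outer)) {
    sol <- solve_steady(params, y_p = y_p, U_p = U, state = if (is.null(sol)) state else sol)
    FE <- electric_force(sol)$axial
    Ff <- sol$force_f_axial
    Ftot <- FE + Ff
    # probe the drag slope with the cached factorisation
    dU <- max(abs(U) * 0.5, 1e-3)
    st2 <- solve_stokes(sol$mesh, params$elec, f = sol$body_force,
                        U_p = U + dU, cache = sol$caches$stokes)
    k <- (st2$force_axial - Ff) / dU
    if (!is.finite(k) || k >= 0) {
      stop("force-free iteration failed: non-negative drag slope")
    }
    U_new <- U - Ftot / k
    if (abs(U_new - U) <= max(tol * abs(U_new), 1e-7) ||
        abs(Ftot) <= tol * abs(FE)) {
      U <- U_new
      # final consistent state at the converged velocity
      sol <- solve_steady(params, y_p = y_p, U_p = U, state = sol)
      break
    }
    U <- U_new
    if (outer == max_outer) {
      stop(sprintf(
        "force-free velocity did not converge in %d outer iterations (F=%.3g N at U=%.3g m/s)",
        max_outer, Ftot, U))
    }
  }
  list(U_p = U, sol = sol,
       forces = force_breakdown(sol), outer_iters = outer)
}
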