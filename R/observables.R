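# Ionic current through a cross-section, the base (reference) current, and
# the dimensionless current deviation I* = (I - I0)/I0.

#' Ionic current through a horizontal cross-section
#'
#' Evaluates `I = int_S F (sum_i z_i N_i) . n dS` over the fluid part of the
#' plane `y = y_S` (an annulus between particle and pore wall when the
#' particle straddles the plane). Positive current flows along +y. In
#' planar2d mode the current is reported per metre of depth, doubled to
#' account for the mirror half.
#'
#' @param sol converged `pf_solution`
#' @param y_S axial position of the cross-section (m); default: pore midplane
#' @return object of class `pf_current`: `I` (A), per-species `I_i`, `y_S`
#' @export
ionic_current <- function(sol, y_S = 0) {
  mesh <- sol$mesh
  elec <- sol$params$elec
  fe <- sol$fe
  zs <- y_S * 1e9
  if (zs <= -mesh$dom$Z || zs >= mesh$dom$Z) {
    stop("cross-section lies outside the domain")
  }
  t <- mesh$t
  p <- mesh$p
  z1 <- p[t[, 1], 2]; z2 <- p[t[, 2], 2]; z3 <- p[t[, 3], 2]
  zmin <- pmin(z1, z2, z3)
  zmax <- pmax(z1, z2, z3)
  hit <- which(zmin < zs & zmax >= zs)
  if (length(hit) == 0) stop("cross-section intersects no elements; choose another y_S")
  # intersection of each element with the plane: an r-interval
  r_lo <- r_hi <- numeric(length(hit))
  for (k in seq_along(hit)) {
    v <- t[hit[k], ]
    zz <- p[v, 2]
    rr <- p[v, 1]
    xs <- c()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      za <- zz[e[1]]; zb <- zz[e[2]]
      if ((za - zs) * (zb - zs) <= 0 && za != zb) {
        s <- (zs - za) / (zb - za)
        xs <- c(xs, rr[e[1]] + s * (rr[e[2]] - rr[e[1]]))
      }
    }
    if (length(xs) < 2) { r_lo[k] <- r_hi[k] <- NA; next }
    r_lo[k] <- min(xs)
    r_hi[k] <- max(xs)
  }
  ok <- !is.na(r_lo) & (r_hi - r_lo) > 1e-12
  hit <- hit[ok]; r_lo <- r_lo[ok]; r_hi <- r_hi[ok]
  flux <- species_flux(mesh, elec, sol$phi, sol$conc, vel = sol$vel, fe = fe)
  axi <- fe$axi
  I_i <- numeric(length(elec$z))
  for (i in seq_along(elec$z)) {
    Nz <- flux[[i]][hit, 2] # mol/(m2 s), axial component, per element
    seg <- if (axi) pi * (r_hi^2 - r_lo^2) * 1e-18 else (r_hi - r_lo) * 1e-9 * 2
    I_i[i] <- elec$z[i] * elec$F_const * sum(Nz * seg)
  }
  structure(list(I = sum(I_i), I_i = I_i, y_S = y_S), class = "pf_current")
}

#' @export
print.pf_current <- function(x, ...) {
  cat(sprintf("ionic current at y_S = %.3g nm: I = %.4g nA (species: %s)\n",
              x$y_S * 1e9, x$I * 1e9,
              paste(sprintf("%.4g", x$I_i * 1e9), collapse = ", ")))
  invisible(x)
}

.base_current_cache <- new.env(parent = emptyenv())

#' Base (reference) ionic current
#'
#' The pore current with the particle far from the pore: a full coupled
#' force-free solve at the initial position (0, -300 bp), with the current
#' evaluated at the pore midplane. Cached per parameter set.
#'
#' @param params `pore_params`
#' @param y_far reference particle position (m)
#' @return current (A)
#' @export
base_current <- function(params, y_far = bp_to_m(-300)) {
  key <- paste(collapse = "|", c(
    params$mode, sprintf("%.8g", c(
      unlist(params$elec[c("eps_f", "mu", "T_K")]), params$elec$D,
      params$elec$c0, unlist(params$geom[c("W", "H", "h", "b", "a", "L_p")]),
      params$drive$phi_0, params$particle$sigma_p,
      params$num$bl_frac, params$num$h_bulk, y_far))))
  hitv <- .base_current_cache[[key]]
  if (!is.null(hitv)) return(hitv)
  if (params$drive$phi_0 == 0 && params$particle$sigma_p == 0) {
    .base_current_cache[[key]] <- 0
    return(0)
  }
  ff <- force_free_velocity(params, y_p = y_far)
  I0 <- ionic_current(ff$sol, y_S = 0)$I
  .base_current_cache[[key]] <- I0
  I0
}

#' Dimensionless ionic current deviation
#'
#' `I* = (I - I0)/I0`; positive values are current enhancement, negative
#' values current blockade.
#'
#' @param I current (A)
#' @param I0 base current (A)
#' @return dimensionless deviation
#' @export
current_deviation <- function(I, I0) {
  if (I0 == 0) stop("undefined deviation: base current is zero")
  (I - I0) / I0
}
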