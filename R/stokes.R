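# Incompressible creeping-flow (Stokes) solver with electric body force.
#
# Mixed MINI element (P1 + cubic bubble velocity, P1 pressure), assembled in
# the symmetric-stress form so that the natural boundary condition is the
# true traction: the open top/bottom walls are traction-free (p = 0
# reference), the lateral boundary is free-slip (no penetration, no shear),
# membrane walls are no-slip, and the particle surface moves rigidly with the
# prescribed translation velocity.

#' Electric body force per element
#'
#' `f = -F (z1 c1 + z2 c2) grad phi`, the Coulomb force of the applied and
#' induced fields on the net space charge of the double layers.
#'
#' @param mesh `pf_mesh`
#' @param elec `electrolyte_params`
#' @param phi nodal potential (V)
#' @param conc list of nodal concentrations (mol/m3)
#' @param fe optional precomputed [fem_setup()]
#' @return m x 2 matrix of force density (N/m3) per element
#' @export
electric_body_force <- function(mesh, elec, phi, conc, fe = NULL) {
  if (is.null(fe)) fe <- fem_setup(mesh)
  rho <- numeric(fe$m)
  for (i in seq_along(conc)) {
    rho <- rho + elec$z[i] * field_centroid(fe, conc[[i]])
  }
  rho <- rho * elec$F_const # C/m3
  g <- field_gradient(fe, phi) # V/nm
  cbind(-rho * g$x / 1e-9, -rho * g$y / 1e-9)
}

# velocity basis (3 hats + bubble) values and gradients at the 7-point rule
.mini_basis <- function(fe) {
  nq <- length(.QR7$w)
  val <- array(0, c(fe$m, 4, nq))
  bgx <- array(0, c(fe$m, 4, nq))
  bgy <- array(0, c(fe$m, 4, nq))
  for (q in seq_len(nq)) {
    l <- .QR7$bary[q, ]
    for (a in 1:3) {
      val[, a, q] <- l[a]
      bgx[, a, q] <- fe$gx[, a]
      bgy[, a, q] <- fe$gy[, a]
    }
    val[, 4, q] <- 27 * l[1] * l[2] * l[3]
    bgx[, 4, q] <- 27 * (l[2] * l[3] * fe$gx[, 1] + l[1] * l[3] * fe$gx[, 2] +
                           l[1] * l[2] * fe$gx[, 3])
    bgy[, 4, q] <- 27 * (l[2] * l[3] * fe$gy[, 1] + l[1] * l[3] * fe$gy[, 2] +
                           l[1] * l[2] * fe$gy[, 3])
  }
  list(val = val, gx = bgx, gy = bgy, nq = nq)
}

# Assemble the full MINI Stokes operator (scaled units, viscosity 1).
# Dof ordering: ur nodes, uz nodes, ur bubbles, uz bubbles, pressure nodes.
.stokes_operator <- function(fe) {
  bs <- .mini_basis(fe)
  n <- fe$n; m <- fe$m
  off <- c(ur = 0L, uz = n, urb = 2L * n, uzb = 2L * n + m, p = 2L * n + 2L * m)
  ndof <- 3L * n + 2L * m
  gdof <- function(kind, a) {
    # global dof of local velocity basis a (1:3 nodes, 4 bubble)
    if (a <= 3) off[[kind]] + fe$t[, a] else off[[paste0(kind, "b")]] + seq_len(m)
  }
  ii <- jj <- xx <- list()
  push <- function(i, j, v) {
    k <- length(ii) + 1
    ii[[k]] <<- i; jj[[k]] <<- j; xx[[k]] <<- v
  }
  axi <- fe$axi
  for (a in 1:4) for (b in 1:4) {
    arr <- azz <- arz <- azr <- numeric(m)
    for (q in seq_len(bs$nq)) {
      wq <- .QR7$w[q] * fe$area * fe$w7[, q]
      pax <- bs$gx[, a, q]; pay <- bs$gy[, a, q]
      pbx <- bs$gx[, b, q]; pby <- bs$gy[, b, q]
      arr <- arr + wq * (2 * pax * pbx + pay * pby)
      azz <- azz + wq * (2 * pay * pby + pax * pbx)
      # row ur_a, col uz_b gets mu * psi_b,r * psi_a,z
      arz <- arz + wq * pbx * pay
      azr <- azr + wq * pby * pax
      if (axi) {
        # hoop strain 2 mu (ur/r)(vr/r) * r = 2 ur vr / r
        arr <- arr + 2 * .QR7$w[q] * fe$area *
          bs$val[, a, q] * bs$val[, b, q] / fe$w7[, q]
      }
    }
    push(gdof("ur", a), gdof("ur", b), arr)
    push(gdof("uz", a), gdof("uz", b), azz)
    push(gdof("ur", a), gdof("uz", b), arz)
    push(gdof("uz", a), gdof("ur", b), azr)
  }
  # divergence blocks: row pressure lambda_a, col velocity basis b
  for (a in 1:3) for (b in 1:4) {
    dr <- dz <- numeric(m)
    for (q in seq_len(bs$nq)) {
      la <- .QR7$bary[q, a]
      wq <- .QR7$w[q] * fe$area
      if (axi) {
        dr <- dr - wq * la * (bs$gx[, b, q] * fe$w7[, q] + bs$val[, b, q])
        dz <- dz - wq * la * bs$gy[, b, q] * fe$w7[, q]
      } else {
        dr <- dr - wq * la * bs$gx[, b, q]
        dz <- dz - wq * la * bs$gy[, b, q]
      }
    }
    pa <- off[["p"]] + fe$t[, a]
    push(pa, gdof("ur", b), dr)
    push(pa, gdof("uz", b), dz)
    # symmetric counterpart B^T
    push(gdof("ur", b), pa, dr)
    push(gdof("uz", b), pa, dz)
  }
  K <- .spmat(unlist(ii), unlist(jj), unlist(xx), ndof)
  # tiny pressure regularisation keeps the sparse LU well-pivoted
  Mp <- assemble_mass(fe)
  dia <- Matrix::Diagonal(ndof, 0)
  ip <- off[["p"]] + seq_len(n)
  K[ip, ip] <- K[ip, ip] - 1e-9 * Mp
  list(K = K, off = off, ndof = ndof, bs = bs)
}

# velocity load vector from an element-wise force density (scaled)
.stokes_rhs <- function(fe, op, fscaled, traction_top = 0, traction_bottom = 0) {
  rhs <- numeric(op$ndof)
  bs <- op$bs
  for (a in 1:4) {
    vr <- vz <- numeric(fe$m)
    for (q in seq_len(bs$nq)) {
      wq <- .QR7$w[q] * fe$area * fe$w7[, q]
      vr <- vr + wq * bs$val[, a, q] * fscaled[, 1]
      vz <- vz + wq * bs$val[, a, q] * fscaled[, 2]
    }
    ir <- if (a <= 3) op$off[["ur"]] + fe$t[, a] else op$off[["urb"]] + seq_len(fe$m)
    iz <- if (a <= 3) op$off[["uz"]] + fe$t[, a] else op$off[["uzb"]] + seq_len(fe$m)
    racc <- rowsum(c(vr, vz), c(ir, iz))
    rhs[as.integer(rownames(racc))] <- rhs[as.integer(rownames(racc))] + racc[, 1]
  }
  # prescribed normal traction t = -p_bar n on the open walls
  mesh <- fe$mesh
  for (wall in c("TOP_WALL", "BOTTOM_WALL")) {
    pbar <- if (wall == "TOP_WALL") traction_top else traction_bottom
    if (pbar == 0) next
    ed <- tagged_edges(mesh, wall)
    if (nrow(ed) == 0) next
    en <- edge_normals(mesh, ed)
    lr <- edge_load(mesh, ed, -pbar * en$nx)
    lz <- edge_load(mesh, ed, -pbar * en$ny)
    rhs[op$off[["ur"]] + seq_len(fe$n)] <- rhs[op$off[["ur"]] + seq_len(fe$n)] + lr
    rhs[op$off[["uz"]] + seq_len(fe$n)] <- rhs[op$off[["uz"]] + seq_len(fe$n)] + lz
  }
  rhs
}

.stokes_dirichlet <- function(mesh, op, U_p_scaled) {
  n <- nrow(mesh$p)
  ur0 <- unique(c(nodes_on_tag(mesh, "AXIS"), nodes_on_tag(mesh, "SIDE_BOUNDARY"),
                  nodes_on_tag(mesh, "MEMBRANE_WALL"),
                  nodes_on_tag(mesh, "PARTICLE_SURFACE")))
  uz0 <- nodes_on_tag(mesh, "MEMBRANE_WALL")
  uzp <- setdiff(nodes_on_tag(mesh, "PARTICLE_SURFACE"), uz0)
  fix <- c(op$off[["ur"]] + ur0, op$off[["uz"]] + uz0, op$off[["uz"]] + uzp)
  val <- c(rep(0, length(ur0)), rep(0, length(uz0)), rep(U_p_scaled, length(uzp)))
  list(fix = fix, val = val, particle_uz = op$off[["uz"]] + uzp)
}

#' Solve the Stokes problem for a prescribed particle velocity
#'
#' @param mesh `pf_mesh`
#' @param elec `electrolyte_params` (sets viscosity and the internal scales)
#' @param f element-wise body force density (N/m3), m x 2, or `NULL`
#' @param U_p particle translation velocity (m/s) imposed on the particle
#'   surface
#' @param traction_top,traction_bottom prescribed normal traction (Pa) on the
#'   open walls (used by the Poiseuille benchmark); default traction-free
#' @param cache factorisation cache from a previous call on the same mesh
#' @return list: `vel` (n x 2 m/s, with the bubble part as attribute
#'   `bubble`), `p` (Pa, nodal), `force_axial`, `force_lateral` (N, consistent
#'   reaction force of the fluid on the particle), `cache`
#' @export
solve_stokes <- function(mesh, elec, f = NULL, U_p = 0,
                         traction_top = 0, traction_bottom = 0, cache = NULL) {
  sc <- scales_of(elec)
  if (is.null(cache)) cache <- list(fe = fem_setup(mesh))
  fe <- cache$fe
  if (is.null(cache$op)) cache$op <- .stokes_operator(fe)
  op <- cache$op
  # f_scaled = f L0^2 / (mu U0)
  fs <- if (is.null(f)) matrix(0, fe$m, 2) else f * sc$L0^2 / (elec$mu * sc$U0)
  rhs <- .stokes_rhs(fe, op, fs,
                     traction_top = traction_top / sc$P0,
                     traction_bottom = traction_bottom / sc$P0)
  bc <- .stokes_dirichlet(mesh, op, U_p / sc$U0)
  sol <- fem_solve(op$K, rhs, bc$fix, bc$val, cache = cache$dir)
  cache$dir <- sol$cache
  x <- sol$x
  n <- fe$n; m <- fe$m
  vel <- cbind(x[op$off[["ur"]] + seq_len(n)], x[op$off[["uz"]] + seq_len(n)]) * sc$U0
  attr(vel, "bubble") <- cbind(x[op$off[["urb"]] + seq_len(m)],
                               x[op$off[["uzb"]] + seq_len(m)]) * sc$U0
  p <- x[op$off[["p"]] + seq_len(n)] * sc$P0
  # consistent reaction: residual of the unconstrained system at the
  # particle's velocity rows gives the discrete surface traction integral;
  # outward fluid normal = -outward particle normal, hence the sign
  res <- as.numeric(op$K %*% x - rhs)
  geomfac <- if (fe$axi) 2 * pi else 1
  Fz <- -sum(res[bc$particle_uz]) * geomfac * sc$F0
  list(vel = vel, p = p, force_axial = Fz, force_lateral = 0,
       div_residual = .div_residual(fe, x, op), cache = cache)
}

# relative L2 norm of the discrete divergence (pressure-block residual)
.div_residual <- function(fe, x, op) {
  n <- fe$n
  ip <- op$off[["p"]] + seq_len(n)
  iu <- seq_len(op$off[["p"]])
  Bu <- as.numeric(op$K[ip, iu, drop = FALSE] %*% x[iu])
  un <- sqrt(sum(x[iu]^2))
  if (un == 0) return(0)
  sqrt(sum(Bu^2)) / un
}
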