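# Linear (P1) finite-element machinery on triangle meshes, shared by the
# Poisson, Nernst-Planck and Stokes solvers.
#
# All assembly is done in scaled units: coordinates in nm, potential in RT/F,
# concentrations in units of the bulk value, velocities in eps*phi_T^2/(mu*L0).
# In axisymmetric mode every volume integral carries the meridian weight r
# (the 2*pi factor is applied only in forces/currents); in planar2d the weight
# is 1 and the mesh represents the x >= 0 half of a mirror-symmetric domain.

# interior quadrature rules in barycentric coordinates (rows: points)
.QR3 <- list(
  bary = rbind(c(2, 1, 1), c(1, 2, 1), c(1, 1, 2)) / 4,
  w = rep(1 / 3, 3))
.QR7 <- local({
  a <- 0.4701420641051151
  b <- 0.1012865073234563
  list(bary = rbind(c(1 / 3, 1 / 3, 1 / 3),
                    c(a, a, 1 - 2 * a), c(a, 1 - 2 * a, a), c(1 - 2 * a, a, a),
                    c(b, b, 1 - 2 * b), c(b, 1 - 2 * b, b), c(1 - 2 * b, b, b)),
       w = c(9 / 40, rep(0.1323941527885062, 3), rep(0.1259391805448271, 3)))
})

#' Precompute element data for finite-element assembly
#'
#' @param mesh `pf_mesh`
#' @return list with per-element areas, P1 basis gradients and the
#'   axisymmetric weight evaluated at quadrature points
#' @keywords internal
fem_setup <- function(mesh) {
  p <- mesh$p
  t <- mesh$t
  x1 <- p[t[, 1], 1]; y1 <- p[t[, 1], 2]
  x2 <- p[t[, 2], 1]; y2 <- p[t[, 2], 2]
  x3 <- p[t[, 3], 1]; y3 <- p[t[, 3], 2]
  d <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1) # = 2A > 0
  area <- d / 2
  gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / d
  gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / d
  axi <- mesh$mode == "axisymmetric"
  rq <- function(rule) {
    # weight at each quadrature point: r in axisymmetric mode, 1 in planar
    if (!axi) return(matrix(1, nrow(t), length(rule$w)))
    sapply(seq_along(rule$w), function(q) {
      rule$bary[q, 1] * x1 + rule$bary[q, 2] * x2 + rule$bary[q, 3] * x3
    })
  }
  list(mesh = mesh, n = nrow(p), m = nrow(t), t = t, p = p,
       area = area, gx = gx, gy = gy, axi = axi,
       w3 = rq(.QR3), w7 = rq(.QR7),
       # quadrature point coordinates for the 3-point rule
       q3x = sapply(1:3, function(q) .QR3$bary[q, 1] * x1 + .QR3$bary[q, 2] * x2 + .QR3$bary[q, 3] * x3),
       q3y = sapply(1:3, function(q) .QR3$bary[q, 1] * y1 + .QR3$bary[q, 2] * y2 + .QR3$bary[q, 3] * y3))
}

# triplet accumulation into a sparse matrix
.spmat <- function(ii, jj, xx, n, m = n) {
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, m))
}

#' Assemble stiffness matrix  int w grad(u).grad(v)
#' @keywords internal
assemble_stiffness <- function(fe, coef = 1) {
  wA <- rowSums(fe$w3 * .QR3$w[col(fe$w3)]) * fe$area * coef
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- fe$t[, a]; jj[[k]] <- fe$t[, b]
    xx[[k]] <- (fe$gx[, a] * fe$gx[, b] + fe$gy[, a] * fe$gy[, b]) * wA
  }
  .spmat(unlist(ii), unlist(jj), unlist(xx), fe$n)
}

#' Assemble mass matrix  int w u v
#' @keywords internal
assemble_mass <- function(fe, coef = 1) {
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    v <- numeric(fe$m)
    for (q in 1:3) {
      v <- v + .QR3$w[q] * fe$w3[, q] * .QR3$bary[q, a] * .QR3$bary[q, b]
    }
    ii[[k]] <- fe$t[, a]; jj[[k]] <- fe$t[, b]
    xx[[k]] <- v * fe$area * coef
  }
  .spmat(unlist(ii), unlist(jj), unlist(xx), fe$n)
}

#' Assemble the steady advection-diffusion operator for a species
#'
#' Weak form of div(-grad c + c w) = 0 where `w` is the elementwise drift
#' (migration plus convection) field, with optional streamline (SUPG)
#' stabilisation active only where the cell Peclet number exceeds 1.
#'
#' @param fe from [fem_setup()]
#' @param wx,wy drift components per element
#' @param supg logical
#' @return sparse operator
#' @keywords internal
assemble_advection_diffusion <- function(fe, wx, wy, supg = TRUE) {
  wA <- rowSums(fe$w3 * .QR3$w[col(fe$w3)]) * fe$area
  tau <- NULL
  if (supg) {
    hel <- sqrt(4 * fe$area / sqrt(3)) # size of an equilateral triangle of equal area
    wn <- pmax(sqrt(wx^2 + wy^2), 1e-30)
    pe <- wn * hel / 2
    xi <- ifelse(pe > 1e-4, 1 / tanh(pe) - 1 / pe, pe / 3)
    tau <- hel / (2 * wn) * xi
  }
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    # diffusion
    v <- (fe$gx[, a] * fe$gx[, b] + fe$gy[, a] * fe$gy[, b]) * wA
    # advection: - int w (c w_vec).grad(lambda_a), c ~ lambda_b
    adv <- numeric(fe$m)
    for (q in 1:3) {
      adv <- adv + .QR3$w[q] * fe$w3[, q] * .QR3$bary[q, b]
    }
    v <- v - (wx * fe$gx[, a] + wy * fe$gy[, a]) * adv * fe$area
    if (supg) {
      v <- v + tau * (wx * fe$gx[, a] + wy * fe$gy[, a]) *
        (wx * fe$gx[, b] + wy * fe$gy[, b]) * wA
    }
    ii[[k]] <- fe$t[, a]; jj[[k]] <- fe$t[, b]
    xx[[k]] <- v
  }
  .spmat(unlist(ii), unlist(jj), unlist(xx), fe$n)
}

## ---------------------------------------------------------------------------
## Boundary edge integrals

# edges of the mesh carrying a given tag (k x 2 node indices)
tagged_edges <- function(mesh, tag) {
  mesh$be[mesh$be_tag == PF_TAGS[[tag]], , drop = FALSE]
}

# int_e g lambda_i w ds for constant g per edge; returns load vector.
# Two-point Gauss on each edge (exact for the linear-in-s integrand times w).
edge_load <- function(mesh, edges, g = 1) {
  n <- nrow(mesh$p)
  out <- numeric(n)
  if (nrow(edges) == 0) return(out)
  p1 <- mesh$p[edges[, 1], , drop = FALSE]
  p2 <- mesh$p[edges[, 2], , drop = FALSE]
  len <- sqrt(rowSums((p2 - p1)^2))
  g <- rep_len(g, nrow(edges))
  gs <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))
  axi <- mesh$mode == "axisymmetric"
  acc1 <- acc2 <- numeric(nrow(edges))
  for (s in gs) {
    w <- if (axi) (1 - s) * p1[, 1] + s * p2[, 1] else 1
    acc1 <- acc1 + 0.5 * w * (1 - s)
    acc2 <- acc2 + 0.5 * w * s
  }
  v1 <- g * len * acc1
  v2 <- g * len * acc2
  out_add <- rowsum(c(v1, v2), c(edges[, 1], edges[, 2]))
  out[as.integer(rownames(out_add))] <- out_add[, 1]
  out
}

# int_e g lambda_i lambda_j w ds as a sparse matrix (edge mass), g per edge
edge_mass <- function(mesh, edges, g = 1) {
  n <- nrow(mesh$p)
  if (nrow(edges) == 0) return(.spmat(1, 1, 0, n))
  p1 <- mesh$p[edges[, 1], , drop = FALSE]
  p2 <- mesh$p[edges[, 2], , drop = FALSE]
  len <- sqrt(rowSums((p2 - p1)^2))
  g <- rep_len(g, nrow(edges))
  gs <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))
  axi <- mesh$mode == "axisymmetric"
  a11 <- a12 <- a22 <- numeric(nrow(edges))
  for (s in gs) {
    w <- if (axi) (1 - s) * p1[, 1] + s * p2[, 1] else 1
    a11 <- a11 + 0.5 * w * (1 - s)^2
    a12 <- a12 + 0.5 * w * (1 - s) * s
    a22 <- a22 + 0.5 * w * s^2
  }
  ii <- c(edges[, 1], edges[, 1], edges[, 2], edges[, 2])
  jj <- c(edges[, 1], edges[, 2], edges[, 1], edges[, 2])
  xx <- c(a11, a12, a12, a22) * rep(g * len, 4)
  .spmat(ii, jj, xx, n)
}

# outward unit normal (pointing out of the fluid) and length of boundary
# edges; relies on boundary edges being oriented with the fluid on the left.
edge_normals <- function(mesh, edges) {
  p1 <- mesh$p[edges[, 1], , drop = FALSE]
  p2 <- mesh$p[edges[, 2], , drop = FALSE]
  d <- p2 - p1
  len <- sqrt(rowSums(d^2))
  # fluid on the left of p1->p2 means outward normal is (dy, -dx)/len
  list(nx = d[, 2] / len, ny = -d[, 1] / len, len = len,
       mx = (p1[, 1] + p2[, 1]) / 2, my = (p1[, 2] + p2[, 2]) / 2)
}

## ---------------------------------------------------------------------------
## Constrained solves with factorisation reuse

#' Solve K x = b with Dirichlet constraints
#'
#' @param K full (unconstrained) sparse operator
#' @param b load vector
#' @param fix integer indices of constrained dofs
#' @param val constraint values (recycled)
#' @param cache optional factorisation cache from a previous call with the
#'   same `K` and `fix` (only `b`/`val` may change)
#' @param symmetric use a Cholesky factorisation
#' @return list(x, cache)
#' @keywords internal
fem_solve <- function(K, b, fix, val, cache = NULL, symmetric = FALSE) {
  n <- length(b)
  val <- rep_len(val, length(fix))
  if (is.null(cache)) {
    free <- setdiff(seq_len(n), fix)
    Kff <- K[free, free, drop = FALSE]
    fact <- if (symmetric) {
      Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE, perm = TRUE)
    } else {
      Matrix::lu(Kff)
    }
    cache <- list(fact = fact, free = free, Kfd = K[free, fix, drop = FALSE],
                  symmetric = symmetric)
  }
  x <- numeric(n)
  x[fix] <- val
  rhs <- b[cache$free] - as.numeric(cache$Kfd %*% val)
  x[cache$free] <- as.numeric(Matrix::solve(cache$fact, rhs))
  list(x = x, cache = cache)
}

# nodes carrying a tag (via node_tag, corner priority already applied)
tagged_nodes <- function(mesh, tag) which(mesh$node_tag == PF_TAGS[[tag]])

# nodes lying on any edge with the tag (ignores corner priority)
nodes_on_tag <- function(mesh, tag) {
  sort(unique(as.vector(tagged_edges(mesh, tag))))
}

# P1 gradient of a nodal field, per element
field_gradient <- function(fe, u) {
  list(x = rowSums(fe$gx * matrix(u[fe$t], ncol = 3)),
       y = rowSums(fe$gy * matrix(u[fe$t], ncol = 3)))
}

# nodal field averaged at element centroids
field_centroid <- function(fe, u) rowMeans(matrix(u[fe$t], ncol = 3))
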