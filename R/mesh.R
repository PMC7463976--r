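# Geometry description and unstructured mesh generation.
#
# All meshing is done in the meridian half-plane (r, z) with lengths in nm.
# In axisymmetric mode r is the radial coordinate; in planar2d mode the same
# half-domain is interpreted as the x >= 0 half of a mirror-symmetric channel.

# Boundary tag vocabulary. The top and bottom walls are the open edges of the
# two reservoirs (potential/concentration Dirichlet and open-flow boundaries
# coincide there).
PF_TAGS <- c(AXIS = 1L, TOP_WALL = 2L, BOTTOM_WALL = 3L, SIDE_BOUNDARY = 4L,
             MEMBRANE_WALL = 5L, PARTICLE_SURFACE = 6L)

# deterministic pseudo-jitter in [-0.5, 0.5)
.pf_hash <- function(i) {
  x <- sin(as.numeric(i) * 12.9898 + 78.233) * 43758.5453
  x - floor(x) - 0.5
}

## ---------------------------------------------------------------------------
## Signed distances (nm units)

# distance to capsule surface (negative inside the particle)
.d_particle <- function(r, z, dom) {
  zc <- pmin(pmax(z, dom$z_cap_lo), dom$z_cap_hi)
  sqrt(r^2 + (z - zc)^2) - dom$a
}

# signed distance to a box [x0,x1]x[y0,y1] (negative inside)
.d_box <- function(r, z, x0, x1, y0, y1) {
  dx <- pmax(x0 - r, r - x1)
  dy <- pmax(y0 - z, z - y1)
  inside <- pmax(dx, dy)
  out <- sqrt(pmax(dx, 0)^2 + pmax(dy, 0)^2)
  ifelse(dx < 0 & dy < 0, inside, out)
}

.d_membrane <- function(r, z, dom) .d_box(r, z, dom$rp, dom$R, -dom$hh, dom$hh)

# signed distance to fluid region (negative inside)
.d_fluid <- function(r, z, dom) {
  d <- .d_box(r, z, 0, dom$R, -dom$Z, dom$Z)
  if (dom$has_membrane) d <- pmax(d, -.d_membrane(r, z, dom))
  if (dom$has_particle) d <- pmax(d, -.d_particle(r, z, dom))
  d
}

## ---------------------------------------------------------------------------
## Domain description

#' Build the computational domain for a particle position
#'
#' Constructs the meridian half-plane fluid domain of the nanopore channel:
#' the two reservoirs and pore, minus the membrane and the capped cylindrical
#' particle, with tagged boundary curves. Lengths are handled internally in
#' nanometres.
#'
#' @param geom `sim_geometry` (the particle position `geom$y_p` is used)
#' @param mode `"axisymmetric"` (default) or `"planar2d"`
#' @param membrane set `FALSE` to omit the membrane (used by benchmark
#'   configurations such as unbounded drag)
#' @param particle set `FALSE` to omit the particle (empty channel)
#' @param side_noslip tag the lateral boundary as a rigid wall instead of a
#'   free-slip symmetry boundary (benchmark configurations that need the far
#'   fluid anchored, e.g. drag in a quiescent reservoir)
#' @return object of class `pf_domain`
#' @export
build_domain <- function(geom, mode = c("axisymmetric", "planar2d"),
                         membrane = TRUE, particle = TRUE,
                         side_noslip = FALSE) {
  mode <- match.arg(mode)
  nm <- 1e9
  a <- geom$a * nm
  L_p <- geom$L_p * nm
  yp <- geom$y_p * nm
  dom <- list(
    R = geom$W * nm / 2, Z = (geom$H + geom$h / 2) * nm,
    hh = geom$h * nm / 2, rp = geom$b * nm / 2,
    a = a, L_p = L_p, yp = yp,
    z_cap_lo = yp - (L_p / 2 - a), z_cap_hi = yp + (L_p / 2 - a),
    z_lo = yp - L_p / 2, z_hi = yp + L_p / 2,
    has_membrane = membrane, has_particle = particle,
    side_noslip = side_noslip, mode = mode, geom = geom)
  class(dom) <- "pf_domain"
  if (particle) {
    if (dom$z_hi >= dom$Z || dom$z_lo <= -dom$Z) {
      stop("geometry error: particle does not fit inside the reservoirs at y_p")
    }
    if (membrane && a >= dom$rp) {
      stop("geometry error: particle does not fit pore")
    }
    # clearance guard: the annular gap must admit at least a couple of
    # boundary-layer element rows, otherwise meshing degenerates
    if (membrane && (dom$rp - a) < 0.15 * a) {
      stop("geometry error: particle-wall clearance below mesh resolution")
    }
  }
  dom
}

# analytic meridian area of the fluid region (nm^2)
.domain_area <- function(dom) {
  area <- 2 * dom$R * dom$Z
  if (dom$has_membrane) area <- area - (dom$R - dom$rp) * 2 * dom$hh
  if (dom$has_particle) {
    Lc <- dom$z_cap_hi - dom$z_cap_lo
    area <- area - (dom$a * Lc + pi * dom$a^2 / 2)
  }
  area
}

# Boundary curves as parametric functions over arc length, with tags.
.domain_curves <- function(dom) {
  seg <- function(p0, p1, tag) {
    d <- p1 - p0
    L <- sqrt(sum(d^2))
    list(fun = function(s) cbind(p0[1] + d[1] * s / L, p0[2] + d[2] * s / L),
         L = L, tag = tag)
  }
  arc <- function(centre, a, th0, th1, tag) {
    L <- abs(th1 - th0) * a
    list(fun = function(s) {
      th <- th0 + (th1 - th0) * s / L
      cbind(centre[1] + a * cos(th), centre[2] + a * sin(th))
    }, L = L, tag = tag, min_n = max(3, ceiling(abs(th1 - th0) / 0.45)))
  }
  R <- dom$R; Z <- dom$Z; hh <- dom$hh; rp <- dom$rp
  cv <- list(
    seg(c(0, -Z), c(R, -Z), "BOTTOM_WALL"),
    seg(c(0, Z), c(R, Z), "TOP_WALL"))
  if (dom$has_membrane) {
    cv <- c(cv, list(
      seg(c(R, -Z), c(R, -hh), "SIDE_BOUNDARY"),
      seg(c(R, hh), c(R, Z), "SIDE_BOUNDARY"),
      seg(c(rp, -hh), c(R, -hh), "MEMBRANE_WALL"),
      seg(c(rp, -hh), c(rp, hh), "MEMBRANE_WALL"),
      seg(c(rp, hh), c(R, hh), "MEMBRANE_WALL")))
  } else {
    cv <- c(cv, list(seg(c(R, -Z), c(R, Z), "SIDE_BOUNDARY")))
  }
  if (dom$has_particle) {
    a <- dom$a
    cv <- c(cv, list(
      seg(c(0, -Z), c(0, dom$z_lo), "AXIS"),
      seg(c(0, dom$z_hi), c(0, Z), "AXIS"),
      arc(c(0, dom$z_cap_lo), a, -pi / 2, 0, "PARTICLE_SURFACE"),
      arc(c(0, dom$z_cap_hi), a, 0, pi / 2, "PARTICLE_SURFACE")))
    if (dom$z_cap_hi > dom$z_cap_lo) {
      cv <- c(cv, list(seg(c(a, dom$z_cap_lo), c(a, dom$z_cap_hi),
                           "PARTICLE_SURFACE")))
    }
  } else {
    cv <- c(cv, list(seg(c(0, -Z), c(0, Z), "AXIS")))
  }
  cv
}

## ---------------------------------------------------------------------------
## Size field

# Returns a vectorised function hsize(r, z) in nm.
.size_field <- function(dom, num, elec) {
  lam <- debye_length(elec) * 1e9
  h_bl <- num$bl_frac * lam
  h_bulk <- num$h_bulk * 1e9
  g <- num$grading
  band <- 2 * lam
  gap <- if (dom$has_particle && dom$has_membrane) dom$rp - dom$a else Inf
  h_gap <- min(h_bl, gap / 3)
  function(r, z) {
    h <- rep_len(h_bulk, length(r))
    if (dom$has_particle) {
      dpr <- abs(.d_particle(r, z, dom))
      dp <- pmax(0, dpr - band - h_bl)
      h <- pmin(h, h_bl + g * dp)
      # curvature-limited sizing: the hemispherical caps (radius a) must be
      # resolved regardless of the Debye-length-based layer size
      h <- pmin(h, 0.5 * dom$a + dpr)
    }
    if (dom$has_membrane) {
      dm <- pmax(0, abs(.d_membrane(r, z, dom)) - band - h_bl)
      h <- pmin(h, h_bl + g * dm)
      if (is.finite(gap)) {
        dpore <- .d_box(r, z, 0, dom$rp, -dom$hh, dom$hh)
        h <- pmin(h, h_gap + g * pmax(0, dpore))
      }
    }
    h
  }
}

# Sample one parametric curve at spacing given by hfun; returns node coords
# (endpoints included exactly). A small deterministic tangential jitter on the
# interior samples avoids degenerate cocircular point sets.
.sample_curve <- function(curve, hfun, jitter = 0.08) {
  L <- curve$L
  if (L <= 0) return(NULL)
  sfine <- seq(0, L, length.out = max(16, ceiling(L / 1e-2) + 1))
  # cap the fine resolution to something sane
  if (length(sfine) > 4096) sfine <- seq(0, L, length.out = 4096)
  pts <- curve$fun(sfine)
  w <- 1 / hfun(pts[, 1], pts[, 2])
  cw <- cumsum(c(0, (w[-1] + w[-length(w)]) / 2 * diff(sfine)))
  min_n <- if (!is.null(curve$min_n)) curve$min_n else 1
  n <- max(min_n, round(cw[length(cw)]))
  starget <- approx(cw, sfine, xout = seq(0, cw[length(cw)], length.out = n + 1))$y
  if (n > 1) {
    ds <- diff(starget)
    jit <- .pf_hash(seq_len(n - 1) * 7 + round(starget[2:n] * 1e3)) * jitter
    starget[2:n] <- starget[2:n] + jit * pmin(ds[-n], ds[-1])
  }
  curve$fun(starget)
}

## ---------------------------------------------------------------------------
## Mesh generation

#' Generate a boundary-refined unstructured mesh of a domain
#'
#' Places graded boundary and interior points (boundary-layer refinement to a
#' fraction of the Debye length near the particle and membrane), triangulates
#' them by Delaunay, and relaxes interior nodes with a few force-equilibrium
#' (distmesh-type) iterations. Boundary nodes stay exactly on the boundary
#' curves.
#'
#' @param dom `pf_domain` from [build_domain()]
#' @param num `numerics_params`
#' @param elec `electrolyte_params` (sets the Debye length of the size field)
#' @param niter number of relaxation iterations
#' @return object of class `pf_mesh`: nodes `p` (nm), triangles `t`, boundary
#'   edges `be` with tags `be_tag`, plus size-field metadata
#' @export
generate_mesh <- function(dom, num, elec, niter = 10) {
  hfun <- .size_field(dom, num, elec)
  curves <- .domain_curves(dom)

  bpts_list <- lapply(curves, .sample_curve, hfun = hfun)
  bpts <- do.call(rbind, bpts_list)
  # deduplicate shared curve endpoints
  key <- paste(round(bpts[, 1], 6), round(bpts[, 2], 6))
  keep <- !duplicated(key)
  bpts <- bpts[keep, , drop = FALSE]

  # interior points: multi-level staggered (hex) lattices selected by hsize
  h_min <- min(hfun(bpts[, 1], bpts[, 2]))
  h_bulk <- num$h_bulk * 1e9
  nlev <- max(1, ceiling(log2(h_bulk / h_min)) + 1)
  ipts <- NULL
  for (k in seq_len(nlev) - 1) {
    s <- h_bulk / 2^k
    xs <- seq(s / 2, dom$R, by = s)
    ys <- seq(-dom$Z + s / 2, dom$Z, by = s * sqrt(3) / 2)
    gp <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
    odd <- rep(seq_along(ys) %% 2 == 1, each = length(xs))
    gp[odd, 1] <- gp[odd, 1] - s / 2
    gp <- gp[gp[, 1] > 0, , drop = FALSE]
    hloc <- hfun(gp[, 1], gp[, 2])
    sel <- hloc >= s & (k == 0 | hloc < 2 * s)
    if (k == 0) sel <- hloc >= s
    gp <- gp[sel, , drop = FALSE]
    if (nrow(gp) == 0) next
    # margin from the boundary
    dfl <- .d_fluid(gp[, 1], gp[, 2], dom)
    gp <- gp[dfl < -0.6 * hfun(gp[, 1], gp[, 2]), , drop = FALSE]
    ipts <- rbind(ipts, gp)
  }
  if (!is.null(ipts) && nrow(ipts) > 0) {
    jit <- 0.05 * hfun(ipts[, 1], ipts[, 2])
    ipts[, 1] <- pmax(ipts[, 1] + jit * .pf_hash(seq_len(nrow(ipts))), 1e-6)
    ipts[, 2] <- ipts[, 2] + jit * .pf_hash(seq_len(nrow(ipts)) + 31415L)
  }

  nb <- nrow(bpts)
  p <- rbind(bpts, ipts)
  ni <- nrow(p) - nb
  interior <- seq_len(ni) + nb

  tri <- .cull_triangles(.delaunay_cpp(p), p, dom)
  for (it in seq_len(niter)) {
    tri <- .cull_triangles(.delaunay_cpp(p), p, dom)
    if (it == niter || ni == 0) break
    ed <- .mesh_edges(tri)
    mid <- (p[ed[, 1], , drop = FALSE] + p[ed[, 2], , drop = FALSE]) / 2
    dvec <- p[ed[, 2], , drop = FALSE] - p[ed[, 1], , drop = FALSE]
    len <- sqrt(rowSums(dvec^2))
    he <- hfun(mid[, 1], mid[, 2])
    l0 <- he * 1.12 * sqrt(sum(len^2) / sum(he^2))
    fmag <- pmax(l0 - len, 0) / pmax(len, 1e-12)
    fx <- fmag * dvec[, 1]
    fy <- fmag * dvec[, 2]
    mv <- matrix(0, nrow(p), 2)
    mv[, 1] <- -.tapply_add(fx, ed[, 1], nrow(p)) + .tapply_add(fx, ed[, 2], nrow(p))
    mv[, 2] <- -.tapply_add(fy, ed[, 1], nrow(p)) + .tapply_add(fy, ed[, 2], nrow(p))
    # forces push endpoints apart: endpoint 1 moves along -dvec, endpoint 2 along +dvec
    p[interior, ] <- p[interior, , drop = FALSE] + 0.25 * mv[interior, , drop = FALSE]
    p[interior, 1] <- pmax(p[interior, 1], 1e-6)
    # pull escaped points back inside
    hi <- hfun(p[interior, 1], p[interior, 2])
    d <- .d_fluid(p[interior, 1], p[interior, 2], dom)
    esc <- which(d > -0.25 * hi)
    if (length(esc)) {
      idx <- interior[esc]
      eps <- 1e-4
      gx <- (.d_fluid(p[idx, 1] + eps, p[idx, 2], dom) -
               .d_fluid(p[idx, 1] - eps, p[idx, 2], dom)) / (2 * eps)
      gz <- (.d_fluid(p[idx, 1], p[idx, 2] + eps, dom) -
               .d_fluid(p[idx, 1], p[idx, 2] - eps, dom)) / (2 * eps)
      gn <- pmax(sqrt(gx^2 + gz^2), 1e-9)
      shift <- (d[esc] + 0.45 * hi[esc])
      p[idx, 1] <- pmax(p[idx, 1] - shift * gx / gn, 0)
      p[idx, 2] <- p[idx, 2] - shift * gz / gn
    }
  }

  # cleanup: interior nodes crowding the boundary or involved in low-quality
  # triangles are removed and the points retriangulated (Delaunay locally
  # maximises the minimum angle over the remaining points)
  node_on_bnd <- seq_len(nrow(p)) <= nb
  if (ni > 0) {
    bidx <- which(node_on_bnd)
    iidx <- which(!node_on_bnd)
    h_i <- hfun(p[iidx, 1], p[iidx, 2])
    mind <- rep(Inf, length(iidx))
    for (chunk in split(seq_along(iidx), ceiling(seq_along(iidx) / 500))) {
      d2 <- outer(p[iidx[chunk], 1], p[bidx, 1], "-")^2 +
        outer(p[iidx[chunk], 2], p[bidx, 2], "-")^2
      mind[chunk] <- sqrt(apply(d2, 1, min))
    }
    keep <- setdiff(seq_len(nrow(p)), iidx[mind < 0.48 * h_i])
  } else {
    keep <- seq_len(nrow(p))
  }
  for (pass in 1:8) {
    pk <- p[keep, , drop = FALSE]
    tri <- .cull_triangles(.delaunay_cpp(pk), pk, dom)
    bad <- which(.tri_min_angle(pk, tri) < 16)
    if (!length(bad)) break
    badnodes <- unique(as.vector(tri[bad, , drop = FALSE]))
    movable <- badnodes[!node_on_bnd[keep[badnodes]]]
    if (!length(movable)) break
    if (pass <= 4) {
      # relocate offending interior nodes to the mean of their neighbours
      ed <- .mesh_edges(tri)
      for (v in movable) {
        nb_v <- c(ed[ed[, 1] == v, 2], ed[ed[, 2] == v, 1])
        if (length(nb_v) >= 3) {
          cand <- colMeans(pk[nb_v, , drop = FALSE])
          if (.d_fluid(cand[1], cand[2], dom) < 0) p[keep[v], ] <- cand
        }
      }
    } else {
      keep <- keep[-movable]
    }
  }
  pk <- p[keep, , drop = FALSE]
  tri <- .cull_triangles(.delaunay_cpp(pk), pk, dom)
  .finalize_mesh(pk, tri, dom, num, elec)
}

# minimum interior angle (degrees) per triangle
.tri_min_angle <- function(p, t) {
  l1 <- sqrt(rowSums((p[t[, 2], , drop = FALSE] - p[t[, 3], , drop = FALSE])^2))
  l2 <- sqrt(rowSums((p[t[, 1], , drop = FALSE] - p[t[, 3], , drop = FALSE])^2))
  l3 <- sqrt(rowSums((p[t[, 1], , drop = FALSE] - p[t[, 2], , drop = FALSE])^2))
  ang <- function(a, b, cc) acos(pmin(1, pmax(-1, (b^2 + cc^2 - a^2) / (2 * b * cc))))
  A1 <- ang(l1, l2, l3)
  A2 <- ang(l2, l1, l3)
  pmin(A1, A2, pi - A1 - A2) * 180 / pi
}

.tapply_add <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

.tri_area <- function(p, t) {
  a <- p[t[, 1], , drop = FALSE]
  b <- p[t[, 2], , drop = FALSE]
  cc <- p[t[, 3], , drop = FALSE]
  ((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
      (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])) / 2
}

.cull_triangles <- function(tri, p, dom) {
  cen_r <- (p[tri[, 1], 1] + p[tri[, 2], 1] + p[tri[, 3], 1]) / 3
  cen_z <- (p[tri[, 1], 2] + p[tri[, 2], 2] + p[tri[, 3], 2]) / 3
  keep <- .d_fluid(cen_r, cen_z, dom) < 0
  tri <- tri[keep, , drop = FALSE]
  ar <- .tri_area(p, tri)
  flip <- ar < 0
  if (any(flip)) tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  tri[abs(ar) > 1e-12, , drop = FALSE]
}

# all unique edges of a triangulation
.mesh_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[!duplicated(e), , drop = FALSE]
}

# boundary edges: appear in exactly one triangle; returned oriented CCW
# (domain on the left)
.boundary_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  single <- names(cnt)[cnt == 1]
  e[key %in% single, , drop = FALSE]
}

.classify_edges <- function(be, p, dom) {
  mr <- (p[be[, 1], 1] + p[be[, 2], 1]) / 2
  mz <- (p[be[, 1], 2] + p[be[, 2], 2]) / 2
  d <- cbind(
    AXIS = abs(mr),
    TOP_WALL = abs(mz - dom$Z),
    BOTTOM_WALL = abs(mz + dom$Z),
    SIDE_BOUNDARY = abs(mr - dom$R),
    MEMBRANE_WALL = if (dom$has_membrane) abs(.d_membrane(mr, mz, dom)) else Inf,
    PARTICLE_SURFACE = if (dom$has_particle) abs(.d_particle(mr, mz, dom)) else Inf)
  tags <- colnames(d)[max.col(-d, ties.method = "first")]
  if (isTRUE(dom$side_noslip)) tags[tags == "SIDE_BOUNDARY"] <- "MEMBRANE_WALL"
  PF_TAGS[tags]
}

.finalize_mesh <- function(p, tri, dom, num = NULL, elec = NULL) {
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(p))
  remap[used] <- seq_along(used)
  p <- p[used, , drop = FALSE]
  tri <- matrix(remap[tri], ncol = 3)
  be <- .boundary_edges(tri)
  tag <- .classify_edges(be, p, dom)
  node_tag <- integer(nrow(p)) # 0 = interior; boundary nodes get a tag
  # particle/membrane (Dirichlet-strongest) tags win at corners
  for (tg in c("TOP_WALL", "BOTTOM_WALL", "SIDE_BOUNDARY", "AXIS",
               "MEMBRANE_WALL", "PARTICLE_SURFACE")) {
    sel <- tag == PF_TAGS[[tg]]
    node_tag[unique(as.vector(be[sel, ]))] <- PF_TAGS[[tg]]
  }
  structure(list(p = p, t = tri, be = be, be_tag = unname(tag),
                 node_tag = node_tag, dom = dom,
                 lambda_nm = if (!is.null(elec)) debye_length(elec) * 1e9 else NA_real_,
                 bl_h = if (!is.null(num) && !is.null(elec))
                   num$bl_frac * debye_length(elec) * 1e9 else NA_real_,
                 mode = dom$mode),
            class = "pf_mesh")
}

#' @export
print.pf_mesh <- function(x, ...) {
  q <- mesh_quality(x)
  cat(sprintf("pf_mesh: %d nodes, %d triangles, %d boundary edges (%s)\n",
              nrow(x$p), nrow(x$t), nrow(x$be), x$mode))
  cat(sprintf("  min angle %.1f deg, max aspect %.2f, bl violations: %d\n",
              q$min_angle, q$max_aspect, q$bl_violations))
  invisible(x)
}

#' Mesh quality report
#'
#' @param mesh `pf_mesh`
#' @return list with `min_angle` (degrees), `max_aspect` (longest/shortest
#'   edge ratio), `bl_violations` (edges inside the boundary-layer band longer
#'   than the target), `n_nodes`, `n_tri`
#' @export
mesh_quality <- function(mesh) {
  p <- mesh$p
  t <- mesh$t
  if (nrow(t) == 0) stop("empty mesh")
  l1 <- sqrt(rowSums((p[t[, 2], , drop = FALSE] - p[t[, 3], , drop = FALSE])^2))
  l2 <- sqrt(rowSums((p[t[, 1], , drop = FALSE] - p[t[, 3], , drop = FALSE])^2))
  l3 <- sqrt(rowSums((p[t[, 1], , drop = FALSE] - p[t[, 2], , drop = FALSE])^2))
  ang <- function(a, b, cc) acos(pmin(1, pmax(-1, (b^2 + cc^2 - a^2) / (2 * b * cc))))
  A1 <- ang(l1, l2, l3); A2 <- ang(l2, l1, l3); A3 <- pi - A1 - A2
  min_angle <- min(A1, A2, A3) * 180 / pi
  aspect <- pmax(l1, l2, l3) / pmin(l1, l2, l3)
  viol <- 0L
  if (!is.na(mesh$bl_h)) {
    ed <- .mesh_edges(t)
    len <- sqrt(rowSums((p[ed[, 1], , drop = FALSE] - p[ed[, 2], , drop = FALSE])^2))
    band <- 2 * mesh$lambda_nm
    # an edge is in the boundary layer when both endpoints are within the band
    inband <- rep(FALSE, nrow(ed))
    for (feat in c("particle", "membrane")) {
      if (feat == "particle" && !mesh$dom$has_particle) next
      if (feat == "membrane" && !mesh$dom$has_membrane) next
      dfn <- if (feat == "particle") .d_particle else .d_membrane
      d1 <- abs(dfn(p[ed[, 1], 1], p[ed[, 1], 2], mesh$dom))
      d2 <- abs(dfn(p[ed[, 2], 1], p[ed[, 2], 2], mesh$dom))
      inband <- inband | (d1 < band & d2 < band)
    }
    viol <- sum(inband & len > 1.35 * mesh$bl_h)
  }
  list(min_angle = min_angle, max_aspect = max(aspect),
       bl_violations = as.integer(viol),
       n_nodes = nrow(p), n_tri = nrow(t))
}

## ---------------------------------------------------------------------------
## Structured rectangle meshes (benchmark fixtures)

#' Structured triangular mesh of a rectangle
#'
#' Used by the closed-form benchmark problems (1-D double layer slabs,
#' Poiseuille and electroosmotic channels). Optional geometric grading packs
#' nodes toward the low-x wall to resolve a double layer.
#'
#' @param x0,x1,y0,y1 rectangle extents (nm)
#' @param nx,ny number of node columns/rows
#' @param tags named character vector mapping sides (`left`, `right`, `bottom`,
#'   `top`) to tag names from `PF_TAGS`
#' @param grade_x optional ratio of largest to smallest x spacing (> 1 packs
#'   nodes toward `x0`)
#' @param mode `"planar2d"` or `"axisymmetric"`
#' @return `pf_mesh`
#' @export
mesh_rectangle <- function(x0, x1, y0, y1, nx, ny,
                           tags = c(left = "AXIS", right = "SIDE_BOUNDARY",
                                    bottom = "BOTTOM_WALL", top = "TOP_WALL"),
                           grade_x = 1, mode = "planar2d") {
  xs <- if (grade_x > 1) {
    t <- seq(0, 1, length.out = nx)
    r <- grade_x^(1 / (nx - 2))
    x0 + (x1 - x0) * (r^(t * (nx - 1)) - 1) / (r^(nx - 1) - 1)
  } else seq(x0, x1, length.out = nx)
  ys <- seq(y0, y1, length.out = ny)
  p <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  id <- function(i, j) (j - 1) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  # split each quad along alternating diagonals for isotropy
  flip <- (i + j) %% 2 == 0
  t1 <- cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1))
  t2 <- cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1))
  t1f <- cbind(id(i, j), id(i + 1, j), id(i, j + 1))
  t2f <- cbind(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
  tri <- rbind(t1[!flip, ], t2[!flip, ], t1f[flip, ], t2f[flip, ])
  be <- .boundary_edges(tri)
  mr <- (p[be[, 1], 1] + p[be[, 2], 1]) / 2
  mz <- (p[be[, 1], 2] + p[be[, 2], 2]) / 2
  side <- rep("right", nrow(be))
  tol <- 1e-9 * max(abs(c(x0, x1, y0, y1)), 1)
  side[abs(mr - x0) < tol] <- "left"
  side[abs(mz - y0) < tol] <- "bottom"
  side[abs(mz - y1) < tol] <- "top"
  tag <- PF_TAGS[tags[side]]
  node_tag <- integer(nrow(p))
  for (tg in unique(tags)) {
    sel <- tag == PF_TAGS[[tg]]
    node_tag[unique(as.vector(be[sel, ]))] <- PF_TAGS[[tg]]
  }
  # corner convention: wall tags override open edges
  for (tg in c("MEMBRANE_WALL", "PARTICLE_SURFACE")) {
    if (tg %in% tags) {
      sel <- tag == PF_TAGS[[tg]]
      node_tag[unique(as.vector(be[sel, ]))] <- PF_TAGS[[tg]]
    }
  }
  dom <- structure(list(R = x1, Z = max(abs(c(y0, y1))), has_membrane = FALSE,
                        has_particle = FALSE, mode = mode, geom = NULL),
                   class = "pf_domain")
  structure(list(p = p, t = tri, be = be, be_tag = unname(tag),
                 node_tag = node_tag, dom = dom,
                 lambda_nm = NA_real_, bl_h = NA_real_, mode = mode),
            class = "pf_mesh")
}
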