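# Fixed-point coupling of the Poisson, Nernst-Planck and Stokes solvers to a
# self-consistent steady state at one particle position and velocity.
#
# Each outer iteration performs: (1) a Gummel-linearised Poisson solve (the
# Boltzmann response of the ions is treated implicitly, which keeps the
# electrostatic fixed point contractive at the surface charge used here);
# (2) linear Nernst-Planck solves per species with frozen potential and flow;
# (3) the electric body force; (4) a Stokes solve with the cached
# factorisation. Concentration and velocity updates are under-relaxed.

#' Solve the coupled steady electrokinetic problem
#'
#' @param params `pore_params`
#' @param y_p particle axial position (m); defaults to `params$geom$y_p`
#' @param U_p particle translation velocity (m/s) imposed on the particle
#' @param state optional previous `pf_solution` used as warm start. When its
#'   mesh was built for the same position the mesh, caches and fields are
#'   reused; otherwise its fields are mapped onto the new mesh by nearest
#'   node as the initial iterate.
#' @param mesh optional pre-built `pf_mesh` (must match `y_p`)
#' @param sigma_wall optional surface charge (C/m2) on `MEMBRANE_WALL` edges
#'   (benchmark fixtures)
#' @param stop_on_fail raise a convergence error when the Picard loop does
#'   not reach tolerance (default); otherwise return with `converged = FALSE`
#' @param quiet suppress the per-solve log line
#' @return object of class `pf_solution`: fields `phi` (V), `conc` (mol/m3),
#'   `vel` (m/s, bubble part as attribute), `p` (Pa), the mesh, convergence
#'   history and solver caches for warm restarts
#' @export
solve_steady <- function(params, y_p = NULL, U_p = 0, state = NULL,
                         mesh = NULL, sigma_wall = 0, stop_on_fail = TRUE,
                         quiet = TRUE) {
  elec <- params$elec
  num <- params$num
  if (is.null(y_p)) y_p <- params$geom$y_p
  geom <- params$geom
  geom$y_p <- y_p

  reuse <- !is.null(state) && !is.null(state$mesh) &&
    isTRUE(all.equal(state$y_p, y_p)) && is.null(mesh)
  if (reuse) {
    mesh <- state$mesh
    caches <- state$caches
  } else {
    if (is.null(mesh)) {
      dom <- build_domain(geom, mode = params$mode)
      mesh <- generate_mesh(dom, num, elec)
    }
    caches <- list()
  }
  n <- nrow(mesh$p)
  if (is.null(caches$pois)) caches$pois <- list(fe = fem_setup(mesh))
  fe <- caches$pois$fe
  if (is.null(caches$np)) caches$np <- list(fe = fe)
  if (is.null(caches$stokes)) caches$stokes <- list(fe = fe)

  # initial iterate
  if (reuse) {
    phi <- state$phi
    conc <- state$conc
    vel <- state$vel
  } else if (!is.null(state) && !is.null(state$mesh)) {
    map <- .nearest_node(state$mesh$p, mesh$p)
    phi <- state$phi[map]
    conc <- lapply(state$conc, function(ci) ci[map])
    vel <- state$vel[map, , drop = FALSE]
    attr(vel, "bubble") <- NULL
  } else {
    phi <- numeric(n)
    conc <- lapply(seq_along(elec$z), function(i) rep(elec$c0[i], n))
    vel <- NULL
  }

  omega <- num$relax
  hist <- data.frame(iter = integer(), residual = numeric(),
                     stage = character())
  converged <- FALSE
  st <- NULL
  f <- NULL

  # Cold starts first converge the electrostatic subproblem (Poisson +
  # Nernst-Planck with a quiescent fluid). The electroosmotic feedback on the
  # ion distributions is weak (small Peclet numbers), but coupling the flow
  # to a far-from-consistent charge field excites a violent transient; the
  # staged start removes it at negligible cost.
  if (is.null(vel)) {
    for (it0 in seq_len(num$picard_max)) {
      ps <- solve_poisson(mesh, elec, drive = params$drive,
                          particle = params$particle, conc = conc,
                          sigma_wall = sigma_wall, phi_prev = phi,
                          cache = caches$pois)
      caches$pois <- ps$cache
      dphi <- .rel_change(ps$phi, phi, floor = 1e-4)
      phi <- ps$phi
      nps <- solve_nernst_planck(mesh, elec, phi, vel = NULL, U_p = U_p,
                                 check = FALSE, supg = isTRUE(num$supg),
                                 cache = caches$np)
      caches$np <- nps$cache
      dc <- 0
      for (i in seq_along(conc)) {
        dc <- max(dc, .rel_change(nps$conc[[i]], conc[[i]]))
        conc[[i]] <- conc[[i]] + omega * (nps$conc[[i]] - conc[[i]])
      }
      hist <- rbind(hist, data.frame(iter = nrow(hist) + 1,
                                     residual = max(dphi, dc),
                                     stage = "electrostatic"))
      if (max(dphi, dc) < max(num$picard_tol, 0.02)) break
    }
  }

  for (it in seq_len(num$picard_max)) {
    ps <- solve_poisson(mesh, elec, drive = params$drive,
                        particle = params$particle, conc = conc,
                        sigma_wall = sigma_wall, phi_prev = phi,
                        cache = caches$pois)
    caches$pois <- ps$cache
    dphi <- .rel_change(ps$phi, phi, floor = 1e-4)
    phi <- ps$phi

    nps <- solve_nernst_planck(mesh, elec, phi, vel = vel, U_p = U_p,
                               check = FALSE, supg = isTRUE(num$supg),
                               cache = caches$np)
    caches$np <- nps$cache
    dc <- 0
    for (i in seq_along(conc)) {
      dc <- max(dc, .rel_change(nps$conc[[i]], conc[[i]]))
      conc[[i]] <- conc[[i]] + omega * (nps$conc[[i]] - conc[[i]])
    }

    f <- electric_body_force(mesh, elec, phi, conc, fe = fe)
    st <- solve_stokes(mesh, elec, f = f, U_p = U_p, cache = caches$stokes)
    caches$stokes <- st$cache
    du <- .rel_change(as.numeric(st$vel),
                      if (is.null(vel)) numeric(2 * n) else as.numeric(vel[, 1:2]),
                      floor = 1e-6)
    vnew <- if (is.null(vel)) st$vel else {
      v <- vel[, 1:2] + omega * (st$vel - vel[, 1:2])
      attr(v, "bubble") <- attr(st$vel, "bubble")
      v
    }
    vel <- vnew

    res <- max(dphi, dc, du)
    hist <- rbind(hist, data.frame(iter = nrow(hist) + 1, residual = res,
                                   stage = "coupled"))
    if (res < num$picard_tol && it >= 2) {
      converged <- TRUE
      break
    }
  }
  if (!converged && stop_on_fail) {
    stop(structure(class = c("pf_convergence_error", "error", "condition"),
                   list(message = sprintf(
                     "convergence error: residual %.3g after %d iterations",
                     utils::tail(hist$residual, 1), nrow(hist)),
                     call = sys.call(), history = hist)))
  }
  cmin <- min(vapply(conc, min, 0))
  if (converged && cmin < -1e-6 * elec$c0[1]) {
    warning(sprintf("concentration undershoot %.3g mol/m3; boundary layer may be under-resolved", cmin))
  }
  if (!quiet) {
    message(sprintf(
      '{"y_p_bp": %.6g, "U_p": %.6g, "iterations": %d, "residual": %.3g, "elements": %d}',
      m_to_bp(y_p), U_p, nrow(hist), utils::tail(hist$residual, 1), nrow(mesh$t)))
  }
  # the state carries the last (unrelaxed) Stokes solution so that the
  # stored pressure, velocity and reaction force are mutually consistent
  # with the final potential and concentration fields
  structure(list(mesh = mesh, phi = phi, conc = conc, vel = st$vel, p = st$p,
                 y_p = y_p, U_p = U_p, params = params, history = hist,
                 converged = converged, caches = caches, fe = fe,
                 body_force = f, force_f_axial = st$force_axial),
            class = "pf_solution")
}

# relative L2 change with an absolute floor so that fields that are
# physically zero (e.g. the flow around an uncharged particle) register as
# converged rather than as 100% relative noise
.rel_change <- function(new, old, floor = 0) {
  den <- max(sqrt(sum(new^2)), floor * sqrt(length(new)))
  if (den == 0) return(if (sqrt(sum(old^2)) > 0) 1 else 0)
  sqrt(sum((new - old)^2)) / den
}

# index of nearest point in `from` for each row of `to` (chunked brute force)
.nearest_node <- function(from, to) {
  out <- integer(nrow(to))
  for (chunk in split(seq_len(nrow(to)), ceiling(seq_len(nrow(to)) / 512))) {
    d2 <- outer(to[chunk, 1], from[, 1], "-")^2 +
      outer(to[chunk, 2], from[, 2], "-")^2
    out[chunk] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' @export
print.pf_solution <- function(x, ...) {
  cat(sprintf("pf_solution at y_p = %.1f bp, U_p = %.4g mm/s (%s)\n",
              m_to_bp(x$y_p), x$U_p * 1e3,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  %d iterations, final residual %.3g, %d elements\n",
              nrow(x$history), utils::tail(x$history$residual, 1), nrow(x$mesh$t)))
  invisible(x)
}
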