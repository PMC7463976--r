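# Trajectory sweeps: per-position force-free solves, attached current
# observables, reconstructed translocation time, and extremum location.

#' Sweep the particle along a position grid
#'
#' Runs a force-free coupled solve at every grid position (warm-started from
#' the previous position), attaches the pore current and the dimensionless
#' deviation I*, and reconstructs the translocation time by quadrature of
#' 1/U_p. Positions whose solve fails are flagged and the sweep continues.
#'
#' @param params `pore_params`
#' @param grid_bp particle positions (bp); default `params$num$grid_bp`
#' @param y_S cross-section for the current (m)
#' @param I0 base current (A); computed from the first grid position when
#'   `NULL` (the reference state with the particle far below the pore)
#' @param progress print one line per position
#' @return object of class `pf_trajectory`: a data frame with columns
#'   `yp_bp`, `yp_m`, `Up_m_per_s`, `Up_mm_per_s`, `I_A`, `I_star`, `t_s`,
#'   `converged`, with the run parameters attached as attributes
#' @export
sweep_trajectory <- function(params, grid_bp = NULL, y_S = 0, I0 = NULL,
                             progress = FALSE) {
  if (is.null(grid_bp)) grid_bp <- params$num$grid_bp
  grid_bp <- sort(unique(grid_bp))
  n <- length(grid_bp)
  rows <- data.frame(yp_bp = grid_bp, yp_m = bp_to_m(grid_bp),
                     Up_m_per_s = NA_real_, Up_mm_per_s = NA_real_,
                     I_A = NA_real_, I_star = NA_real_, t_s = NA_real_,
                     converged = FALSE)
  state <- NULL
  for (k in seq_len(n)) {
    res <- tryCatch(
      force_free_velocity(params, y_p = bp_to_m(grid_bp[k]), state = state),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("position %g bp skipped: %s", grid_bp[k],
                      conditionMessage(res)))
      next
    }
    state <- res$sol
    # drop heavyweight caches from the retained state copy
    I <- tryCatch(ionic_current(res$sol, y_S = y_S)$I, error = function(e) NA_real_)
    rows$Up_m_per_s[k] <- res$U_p
    rows$Up_mm_per_s[k] <- res$U_p * 1e3
    rows$I_A[k] <- I
    rows$converged[k] <- isTRUE(res$sol$converged)
    if (progress) {
      message(sprintf("y_p = %6.1f bp: U_p = %8.3f mm/s, I = %.4g nA",
                      grid_bp[k], res$U_p * 1e3, I * 1e9))
    }
  }
  if (is.null(I0)) {
    I0 <- rows$I_A[which(rows$converged)[1]]
  }
  rows$I_star <- (rows$I_A - I0) / I0
  rows$t_s <- .reconstruct_time(rows$yp_m, rows$Up_m_per_s)
  structure(rows,
            class = c("pf_trajectory", "data.frame"),
            I0 = I0, params = params,
            meta = list(E_nom = params$drive$E_nom,
                        L_p_bp = m_to_bp(params$geom$L_p),
                        sigma_p = params$particle$sigma_p,
                        C0 = params$elec$c0[1], mode = params$mode,
                        bl_frac = params$num$bl_frac,
                        h_bulk = params$num$h_bulk))
}

# trapezoid quadrature of t(y) = int dy / U(y) over converged rows
.reconstruct_time <- function(y, U) {
  t <- rep(NA_real_, length(y))
  ok <- which(is.finite(U) & U != 0)
  if (length(ok) < 2) return(t)
  t[ok[1]] <- 0
  for (j in seq_along(ok)[-1]) {
    i0 <- ok[j - 1]; i1 <- ok[j]
    t[ok[j]] <- t[i0] + (y[i1] - y[i0]) * 0.5 * (1 / U[i0] + 1 / U[i1])
  }
  t
}

#' Locate an extremum of a trajectory quantity
#'
#' Finds the discrete extremum over converged rows and refines it by a
#' quadratic fit through the three bracketing points (exact for a parabola).
#' An extremum on the grid boundary is flagged as unbracketed.
#'
#' @param traj `pf_trajectory` (or data frame with `yp_bp` and the quantity)
#' @param quantity column name, e.g. `"Up_m_per_s"` or `"I_star"`
#' @param kind `"max"` or `"min"`
#' @return list: `yp_bp`, `value` (refined), `bracketed`
#' @export
find_extremum <- function(traj, quantity = "Up_m_per_s",
                          kind = c("max", "min")) {
  kind <- match.arg(kind)
  ok <- traj$converged & is.finite(traj[[quantity]])
  x <- traj$yp_bp[ok]
  v <- traj[[quantity]][ok]
  if (length(x) < 3) stop("need at least 3 converged rows")
  i <- if (kind == "max") which.max(v) else which.min(v)
  if (i == 1 || i == length(x)) {
    return(list(yp_bp = x[i], value = v[i], bracketed = FALSE))
  }
  # quadratic through the three bracketing points
  x3 <- x[(i - 1):(i + 1)]
  v3 <- v[(i - 1):(i + 1)]
  cf <- unname(solve(cbind(1, x3, x3^2), v3))
  if (cf[3] == 0) return(list(yp_bp = x3[2], value = v3[2], bracketed = TRUE))
  xv <- unname(-cf[2] / (2 * cf[3]))
  vv <- unname(cf[1] + cf[2] * xv + cf[3] * xv^2)
  # keep the vertex inside the bracket; fall back to the grid point otherwise
  if (xv < x3[1] || xv > x3[3]) {
    xv <- x3[2]
    vv <- v3[2]
  }
  list(yp_bp = xv, value = vv, bracketed = TRUE)
}

#' @export
print.pf_trajectory <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("pf_trajectory: E = %g MV/m, L_p = %g bp, %d/%d rows converged\n",
              meta$E_nom / 1e6, meta$L_p_bp, sum(x$converged), nrow(x)))
  pk <- try(find_extremum(x, "Up_m_per_s", "max"), silent = TRUE)
  if (!inherits(pk, "try-error")) {
    cat(sprintf("  peak U_p = %.1f mm/s at y_p = %.1f bp; I0 = %.4g nA\n",
                pk$value * 1e3, pk$yp_bp, attr(x, "I0") * 1e9))
  }
  NextMethod()
}

#' Plot a trajectory
#'
#' Velocity and current-deviation curves against particle position, in the
#' style of the parameter-study figures.
#'
#' @param x `pf_trajectory`
#' @param which `"velocity"`, `"current"` or `"both"`
#' @param ... passed to [plot()]
#' @export
plot.pf_trajectory <- function(x, which = c("both", "velocity", "current"), ...) {
  which <- match.arg(which)
  ok <- x$converged
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "velocity")) {
    plot(x$yp_bp[ok], x$Up_mm_per_s[ok], type = "b", pch = 16,
         xlab = "particle position y_p (bp)",
         ylab = "translocation velocity (mm/s)", ...)
    graphics::abline(v = 0, lty = 3)
  }
  if (which %in% c("both", "current")) {
    plot(x$yp_bp[ok], x$I_star[ok], type = "b", pch = 16,
         xlab = "particle position y_p (bp)",
         ylab = "current deviation I*", ...)
    graphics::abline(h = 0, v = 0, lty = 3)
  }
  invisible(x)
}
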