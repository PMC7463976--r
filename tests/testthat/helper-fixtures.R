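# Shared fixtures for the test suite. Expensive coupled solves and sweeps are
# memoised so that several test files can reuse them; everything is generated
# in code and deterministic.

.fx_env <- new.env(parent = emptyenv())

fx <- function(key, expr) {
  if (is.null(.fx_env[[key]])) .fx_env[[key]] <- force(expr)
  .fx_env[[key]]
}

baseline_params <- function(E_nom = 2e6, L_bp = 200, sigma_p = -0.01,
                            profile = "coarse") {
  geom <- sim_geometry(L_p = bp_to_m(L_bp))
  pore_params(geom = geom,
              drive = drive_params(E_nom = E_nom, geom = geom),
              particle = particle_props(sigma_p = sigma_p),
              num = resolution_profile(profile))
}

# force-free solution with the particle at the initial far position
fx_far <- function() fx("far", {
  force_free_velocity(baseline_params(), y_p = bp_to_m(-300))
})

# force-free solution with the particle threading the pore
fx_thread <- function() fx("thread", {
  force_free_velocity(baseline_params(), y_p = 0)
})

# equilibrium double-layer slabs
fx_slab_small <- function() fx("slab_small", dl_slab(-0.002))
fx_slab_base <- function() fx("slab_base", dl_slab(-0.01))

# position grids used by the acceptance sweeps: full range with refinement
# around the entrance and exit peaks where velocity and current vary fastest
acc_grid_full <- function() {
  sort(unique(c(-300, -250, -200, -150, seq(-130, -40, by = 10),
                -20, 0, 20, 40, 60, seq(70, 160, by = 10), 200, 250, 300)))
}
acc_grid_peaks <- function() {
  sort(unique(c(-300, -150, seq(-110, -40, by = 10), 0,
                seq(70, 120, by = 10), 200, 300)))
}

fx_sweep_E <- function(E) fx(paste0("sweep_E", E), {
  grid <- if (E == 2) acc_grid_full() else acc_grid_peaks()
  sweep_trajectory(baseline_params(E_nom = E * 1e6), grid_bp = grid)
})

fx_sweep_L <- function(L_bp) {
  if (L_bp == 200) return(fx_sweep_E(2))
  fx(paste0("sweep_L", L_bp), {
    params <- baseline_params(E_nom = 2e6, L_bp = L_bp)
    I0 <- base_current(params)
    sweep_trajectory(params, grid_bp = seq(-140, 100, by = 20), I0 = I0)
  })
}

# net volume flux (m3/s in axisymmetric mode) through a tagged wall
wall_flux <- function(sol, tag) {
  mesh <- sol$mesh
  ed <- poreflow:::tagged_edges(mesh, tag)
  en <- poreflow:::edge_normals(mesh, ed)
  u1 <- sol$vel[ed[, 1], , drop = FALSE]
  u2 <- sol$vel[ed[, 2], , drop = FALSE]
  un1 <- u1[, 1] * en$nx + u1[, 2] * en$ny
  un2 <- u2[, 1] * en$nx + u2[, 2] * en$ny
  if (mesh$mode == "axisymmetric") {
    r1 <- mesh$p[ed[, 1], 1]
    r2 <- mesh$p[ed[, 2], 1]
    # linear u.n and linear r on each edge, exact integral, times 2 pi
    2 * pi * sum(en$len * 1e-18 *
                   (un1 * (r1 / 3 + r2 / 6) + un2 * (r1 / 6 + r2 / 3)))
  } else {
    sum(en$len * 1e-9 * (un1 + un2) / 2)
  }
}

fx_benchtable <- function() fx("benchtable", run_benchmarks())
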