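#' @useDynLib poreflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods is
#' @importFrom stats approx optimise setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

# Length of one DNA base pair (rise of B-form DNA), used as the axial length unit.
BP_M <- 0.34e-9

#' Electrolyte parameters
#'
#' Fluid and ion-species constants of the background electrolyte. The baseline
#' is an aqueous KCl solution at 10 mol/m3 and 300 K with two monovalent
#' species (K+ and Cl-).
#'
#' @param eps_f fluid permittivity (F/m)
#' @param rho_f fluid density (kg/m3)
#' @param mu dynamic viscosity (Pa s)
#' @param T_K absolute temperature (K)
#' @param z integer valences of the ionic species
#' @param D diffusivities of the species (m2/s)
#' @param c0 bulk concentrations of the species (mol/m3)
#' @param R_gas universal gas constant (J/(mol K))
#' @param F_const Faraday constant (C/mol)
#' @return object of class `electrolyte_params`
#' @export
electrolyte_params <- function(eps_f = 7.08e-10, rho_f = 1e3, mu = 1e-3,
                               T_K = 300,
                               z = c(1, -1),
                               D = c(1.95e-9, 2.03e-9),
                               c0 = c(10, 10),
                               R_gas = 8.314, F_const = 96485) {
  stopifnot(length(z) == length(D), length(D) == length(c0))
  for (nm in c("eps_f", "rho_f", "mu", "T_K", "R_gas", "F_const")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) stop("invariant violated: ", nm, " must be strictly positive")
  }
  if (any(D <= 0) || any(c0 <= 0)) {
    stop("invariant violated: species diffusivities and bulk concentrations must be strictly positive")
  }
  if (abs(sum(z * c0)) > 1e-12 * max(abs(z * c0))) {
    stop("invariant violated: bulk electroneutrality sum(z*c0) = 0")
  }
  structure(list(eps_f = eps_f, rho_f = rho_f, mu = mu, T_K = T_K,
                 z = as.numeric(z), D = as.numeric(D), c0 = as.numeric(c0),
                 R_gas = R_gas, F_const = F_const),
            class = "electrolyte_params")
}

#' Simulation geometry
#'
#' Dimensions of the two-reservoir nanopore channel and of the capped
#' cylindrical particle, all in metres. The particle is a straight cylinder of
#' radius `a` with hemispherical end caps; `L_p` is the end-to-end length
#' including both caps. `y_p` is the axial position of the particle centre with
#' the origin at the pore centre; positive y points from the grounded (lower)
#' reservoir toward the biased (upper) one.
#'
#' @param W reservoir (channel) width (m); the axisymmetric radius is `W/2`
#' @param H height of each reservoir (m)
#' @param h membrane thickness (m)
#' @param b pore diameter (m)
#' @param a particle cap radius (m)
#' @param L_p particle end-to-end length (m)
#' @param y_p particle axial position (m), origin at the pore centre
#' @param x_p lateral offset (m); only 0 is supported by the solvers
#' @return object of class `sim_geometry`
#' @export
sim_geometry <- function(W = 100e-9, H = 200e-9, h = 5e-9, b = 5e-9,
                         a = 1e-9, L_p = 200 * BP_M, y_p = -300 * BP_M,
                         x_p = 0) {
  for (nm in c("W", "H", "h", "b", "a", "L_p")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) stop("invariant violated: ", nm, " must be strictly positive")
  }
  if (2 * a >= b) stop("invariant violated: particle does not fit pore (2a < b required)")
  if (L_p >= 2 * H) stop("invariant violated: particle does not fit a reservoir (L_p < 2H required)")
  if (L_p < 2 * a) stop("invariant violated: L_p >= 2a (caps alone are the minimum particle)")
  if (x_p != 0) stop("only on-axis particles (x_p = 0) are supported")
  structure(list(W = W, H = H, h = h, b = b, a = a, L_p = L_p,
                 y_p = y_p, x_p = x_p, bp_length = BP_M),
            class = "sim_geometry")
}

#' Convert base pairs to metres and back
#'
#' Axial positions and particle lengths are conventionally quoted in base
#' pairs with 1 bp = 0.34 nm.
#'
#' @param x value(s) to convert
#' @return converted value(s)
#' @export
bp_to_m <- function(x) x * BP_M

#' @rdname bp_to_m
#' @export
m_to_bp <- function(x) x / BP_M

#' Electric drive parameters
#'
#' The system is driven by a potential `phi_0` applied at the top (upper
#' reservoir) wall with the bottom wall grounded. The equivalent nominal field
#' is defined as the average field over the full channel height,
#' `E_nom = phi_0 / (2H + h)`. Exactly one of `phi_0`, `E_nom` must be given.
#'
#' @param phi_0 applied potential (V) at the top wall
#' @param E_nom nominal applied field (V/m)
#' @param geom `sim_geometry` used for the conversion
#' @return object of class `drive_params` with both fields populated
#' @export
drive_params <- function(phi_0 = NULL, E_nom = NULL, geom = sim_geometry()) {
  span <- 2 * geom$H + geom$h
  if (is.null(phi_0) && is.null(E_nom)) stop("configuration error: one of phi_0, E_nom required")
  if (is.null(phi_0)) phi_0 <- E_nom * span
  if (is.null(E_nom)) E_nom <- phi_0 / span
  if (abs(phi_0 - E_nom * span) > 1e-12 * max(abs(phi_0), 1e-300)) {
    stop("invariant violated: phi_0 and E_nom inconsistent")
  }
  structure(list(phi_0 = phi_0, E_nom = E_nom, span = span), class = "drive_params")
}

#' Particle surface properties
#'
#' @param sigma_p surface charge density (C/m2); negative for DNA-like particles
#' @param eps_p particle permittivity (F/m); the baseline equals the fluid's
#' @return object of class `particle_props`
#' @export
particle_props <- function(sigma_p = -0.01, eps_p = 7.08e-10) {
  if (!is.finite(sigma_p)) stop("invariant violated: sigma_p must be finite")
  if (!is.finite(eps_p) || eps_p <= 0) stop("invariant violated: eps_p must be strictly positive")
  structure(list(sigma_p = sigma_p, eps_p = eps_p), class = "particle_props")
}

#' Numerical controls
#'
#' @param bl_frac target boundary-layer element size as a fraction of the
#'   Debye length (default 1/3)
#' @param h_bulk bulk element size (m)
#' @param picard_tol relative tolerance of the Picard coupling loop
#' @param picard_max maximum Picard iterations
#' @param relax under-relaxation factor of the Picard loop
#' @param ff_tol relative tolerance of the force-free velocity iteration
#' @param grid_bp position grid for trajectory sweeps (bp)
#' @param grading mesh size growth rate away from boundary layers
#' @param supg streamline stabilisation of the ion drift term
#' @param seed reserved; the solvers are deterministic
#' @return object of class `numerics_params`
#' @export
numerics_params <- function(bl_frac = 1 / 3, h_bulk = 1.6e-9,
                            picard_tol = 0.005, picard_max = 100,
                            relax = 0.5, ff_tol = 1e-3,
                            grid_bp = default_sweep_grid(),
                            grading = 0.35, supg = TRUE, seed = 1L) {
  for (nm in c("bl_frac", "picard_tol", "relax", "ff_tol")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0 || v >= 1) stop("invariant violated: ", nm, " must lie in (0,1)")
  }
  if (picard_max < 1) stop("invariant violated: picard_max >= 1")
  structure(list(bl_frac = bl_frac, h_bulk = h_bulk, picard_tol = picard_tol,
                 picard_max = as.integer(picard_max), relax = relax,
                 ff_tol = ff_tol, grid_bp = grid_bp, grading = grading,
                 supg = isTRUE(supg), seed = as.integer(seed)),
            class = "numerics_params")
}

#' Default sweep grid of particle positions
#'
#' Positions from -300 to +300 bp with a 15 bp step, refined to 5 bp within
#' 120 bp of the pore where velocity and current vary fastest.
#'
#' @param from,to,step,fine_step,fine_halfwidth grid controls in bp
#' @return sorted vector of positions (bp)
#' @export
default_sweep_grid <- function(from = -300, to = 300, step = 15,
                               fine_step = 5, fine_halfwidth = 120) {
  g <- c(seq(from, to, by = step),
         seq(-fine_halfwidth, fine_halfwidth, by = fine_step))
  sort(unique(g))
}

#' Bundle of all model parameters
#'
#' @param elec `electrolyte_params`
#' @param geom `sim_geometry`
#' @param drive `drive_params`
#' @param particle `particle_props`
#' @param num `numerics_params`
#' @param mode coordinate mode, `"axisymmetric"` (default) or `"planar2d"`
#' @return object of class `pore_params`
#' @export
pore_params <- function(elec = electrolyte_params(), geom = sim_geometry(),
                        drive = drive_params(E_nom = 2e6, geom = geom),
                        particle = particle_props(eps_p = elec$eps_f),
                        num = numerics_params(),
                        mode = c("axisymmetric", "planar2d")) {
  mode <- match.arg(mode)
  structure(list(elec = elec, geom = geom, drive = drive, particle = particle,
                 num = num, mode = mode),
            class = "pore_params")
}

#' @export
print.pore_params <- function(x, ...) {
  g <- x$geom
  cat("poreflow parameter set (", x$mode, ")\n", sep = "")
  cat(sprintf("  electrolyte: C0 = %g mol/m3, T = %g K, lambda_D = %.3g nm\n",
              x$elec$c0[1], x$elec$T_K, debye_length(x$elec) * 1e9))
  cat(sprintf("  geometry: W = %g nm, H = %g nm, pore b = %g nm x h = %g nm\n",
              g$W * 1e9, g$H * 1e9, g$b * 1e9, g$h * 1e9))
  cat(sprintf("  particle: a = %g nm, L_p = %g bp, y_p = %g bp, sigma_p = %g C/m2\n",
              g$a * 1e9, m_to_bp(g$L_p), m_to_bp(g$y_p), x$particle$sigma_p))
  cat(sprintf("  drive: phi_0 = %.4g V (E_nom = %g MV/m)\n",
              x$drive$phi_0, x$drive$E_nom / 1e6))
  invisible(x)
}

#' Debye screening length
#'
#' `sqrt(eps_f R T / (F^2 sum z_i^2 c0_i))`: the decay length of the electric
#' double layer. Baseline KCl at 10 mol/m3 and 300 K gives 3.08 nm.
#'
#' @param elec `electrolyte_params`
#' @return length (m)
#' @export
debye_length <- function(elec) {
  sqrt(elec$eps_f * elec$R_gas * elec$T_K /
         (elec$F_const^2 * sum(elec$z^2 * elec$c0)))
}

#' Bulk electrical conductivity (Nernst-Einstein)
#'
#' `(F^2/(R T)) sum z_i^2 D_i c0_i`; baseline KCl 10 mol/m3 gives about
#' 0.149 S/m. Used as the Ohmic oracle for the base current.
#'
#' @param elec `electrolyte_params`
#' @return conductivity (S/m)
#' @export
bulk_conductivity <- function(elec) {
  elec$F_const^2 / (elec$R_gas * elec$T_K) * sum(elec$z^2 * elec$D * elec$c0)
}

#' Thermal voltage RT/F
#' @param elec `electrolyte_params`
#' @return potential (V)
#' @export
thermal_voltage <- function(elec) elec$R_gas * elec$T_K / elec$F_const

# Non-dimensional scales used internally by the solvers: lengths in nm,
# potential in units of RT/F, concentration in units of c0 of species 1,
# velocity in eps*phi_T^2/(mu*L0), pressure mu*U0/L0.
scales_of <- function(elec) {
  phi_T <- thermal_voltage(elec)
  L0 <- 1e-9
  U0 <- elec$eps_f * phi_T^2 / (elec$mu * L0)
  C0 <- elec$c0[1]
  list(L0 = L0, phi_T = phi_T, C0 = C0, U0 = U0,
       P0 = elec$mu * U0 / L0,
       # Poisson/body-force coupling: -lap(phi~) = beta * sum z c~
       beta = elec$F_const * C0 * L0^2 / (elec$eps_f * phi_T),
       # Peclet numbers per species
       Pe = U0 * L0 / elec$D,
       # force scale (meridian integrals carry the 2*pi factor explicitly)
       F0 = elec$eps_f * phi_T^2,
       # current scale per species: I = I0_i * integral(z_i N~_i dS~)
       I0 = elec$F_const * C0 * L0 * elec$D)
}

## ---------------------------------------------------------------------------
## Configuration file handling

.cfg_num <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) return(as.numeric(cfg[[key]]))
  default
}

#' Load a parameter set from a YAML configuration file
#'
#' Flat key-value YAML. All keys are optional and default to the baseline
#' study values. SI keys are named after the parameter fields (`W`, `H`, `h`,
#' `b`, `a`, `L_p`, `y_p`, `sigma_p`, `eps_f`, `eps_p`, `rho_f`, `mu`, `T_K`,
#' `C0`, `D1`, `D2`, `phi_0`, ...); convenience keys `*_nm`, `*_bp` and
#' `E_nom_MV_per_m` are accepted and converted.
#'
#' @param path path to a YAML file, or a YAML string
#' @return `pore_params`
#' @export
load_parameters <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  if (is.null(cfg)) cfg <- list()
  pick <- function(key, default) {
    v <- .cfg_num(cfg, key)
    if (!is.null(v)) return(v)
    v <- .cfg_num(cfg, paste0(key, "_nm"))
    if (!is.null(v)) return(v * 1e-9)
    v <- .cfg_num(cfg, paste0(key, "_bp"))
    if (!is.null(v)) return(bp_to_m(v))
    default
  }
  C0 <- .cfg_num(cfg, "C0", 10)
  elec <- electrolyte_params(
    eps_f = .cfg_num(cfg, "eps_f", 7.08e-10),
    rho_f = .cfg_num(cfg, "rho_f", 1e3),
    mu = .cfg_num(cfg, "mu", 1e-3),
    T_K = .cfg_num(cfg, "T_K", 300),
    z = c(1, -1),
    D = c(.cfg_num(cfg, "D1", 1.95e-9), .cfg_num(cfg, "D2", 2.03e-9)),
    c0 = c(C0, C0))
  geom <- sim_geometry(
    W = pick("W", 100e-9), H = pick("H", 200e-9),
    h = pick("h", 5e-9), b = pick("b", 5e-9),
    a = pick("a", 1e-9), L_p = pick("L_p", bp_to_m(200)),
    y_p = pick("y_p", bp_to_m(-300)),
    x_p = pick("x_p", 0))
  E_nom <- .cfg_num(cfg, "E_nom")
  if (is.null(E_nom) && !is.null(cfg$E_nom_MV_per_m)) E_nom <- as.numeric(cfg$E_nom_MV_per_m) * 1e6
  phi_0 <- .cfg_num(cfg, "phi_0")
  drive <- if (is.null(phi_0) && is.null(E_nom)) {
    drive_params(E_nom = 2e6, geom = geom)
  } else if (!is.null(phi_0)) drive_params(phi_0 = phi_0, geom = geom) else {
    drive_params(E_nom = E_nom, geom = geom)
  }
  particle <- particle_props(sigma_p = .cfg_num(cfg, "sigma_p", -0.01),
                             eps_p = .cfg_num(cfg, "eps_p", elec$eps_f))
  num <- numerics_params(
    bl_frac = .cfg_num(cfg, "bl_frac", 1 / 3),
    h_bulk = pick("h_bulk", 8e-9),
    picard_tol = .cfg_num(cfg, "picard_tol", 0.005),
    picard_max = .cfg_num(cfg, "picard_max", 100),
    relax = .cfg_num(cfg, "relax", 0.5),
    ff_tol = .cfg_num(cfg, "ff_tol", 1e-3),
    grading = .cfg_num(cfg, "grading", 0.35))
  if (!is.null(cfg$grid_bp)) num$grid_bp <- as.numeric(cfg$grid_bp)
  mode <- if (!is.null(cfg$mode)) cfg$mode else "axisymmetric"
  pore_params(elec = elec, geom = geom, drive = drive, particle = particle,
              num = num, mode = mode)
}

#' Serialize a parameter set to YAML
#'
#' Writes a flat key-value document that [load_parameters()] reads back to a
#' field-for-field identical parameter set.
#'
#' @param p `pore_params`
#' @param path optional output file; when `NULL` the YAML string is returned
#' @return path or YAML string, invisibly when written to file
#' @export
write_parameters <- function(p, path = NULL) {
  cfg <- list(
    eps_f = p$elec$eps_f, rho_f = p$elec$rho_f, mu = p$elec$mu,
    T_K = p$elec$T_K, C0 = p$elec$c0[1], D1 = p$elec$D[1], D2 = p$elec$D[2],
    W = p$geom$W, H = p$geom$H, h = p$geom$h, b = p$geom$b, a = p$geom$a,
    L_p = p$geom$L_p, y_p = p$geom$y_p, x_p = p$geom$x_p,
    phi_0 = p$drive$phi_0,
    sigma_p = p$particle$sigma_p, eps_p = p$particle$eps_p,
    bl_frac = p$num$bl_frac, h_bulk = p$num$h_bulk,
    picard_tol = p$num$picard_tol, picard_max = p$num$picard_max,
    relax = p$num$relax, ff_tol = p$num$ff_tol, grading = p$num$grading,
    grid_bp = p$num$grid_bp, mode = p$mode)
  txt <- yaml::as.yaml(cfg)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Resolution profiles
#'
#' Named mesh-resolution presets: `coarse` for fast sweeps, `default` for
#' production fidelity (element counts comparable to the reference study),
#' `fine` doubling the boundary-layer resolution for convergence checks.
#'
#' @param profile one of `"coarse"`, `"default"`, `"fine"`
#' @param num base `numerics_params` to modify
#' @return `numerics_params`
#' @export
resolution_profile <- function(profile = c("coarse", "default", "fine"),
                               num = numerics_params()) {
  profile <- match.arg(profile)
  ov <- switch(profile,
    coarse  = list(bl_frac = 0.55, h_bulk = 14e-9),
    default = list(bl_frac = 1 / 3, h_bulk = 1.6e-9),
    fine    = list(bl_frac = 1 / 6, h_bulk = 1.2e-9))
  num$bl_frac <- ov$bl_frac
  num$h_bulk <- ov$h_bulk
  num
}
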