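# Experiment presets reproducing the parameter studies: field-strength sweeps
# at fixed particle length and length sweeps at fixed field.

#' List the experiment presets
#'
#' `fig3_E{1,2,3}` and `fig6_E{1,2,3}` are the field-strength study
#' (L_p = 200 bp at 1, 2, 3 MV/m; velocity and current views of the same
#' sweep); `fig7_L{50,100,150,200}` and `fig8_L{...}` are the length study at
#' E = 2 MV/m.
#'
#' @return named list of preset definitions (E_nom in V/m, L_p in bp)
#' @export
experiment_presets <- function() {
  out <- list()
  for (E in 1:3) {
    def <- list(E_nom = E * 1e6, L_p_bp = 200)
    out[[paste0("fig3_E", E)]] <- def
    out[[paste0("fig6_E", E)]] <- def
  }
  for (L in c(50, 100, 150, 200)) {
    def <- list(E_nom = 2e6, L_p_bp = L)
    out[[paste0("fig7_L", L)]] <- def
    out[[paste0("fig8_L", L)]] <- def
  }
  out
}

#' Build the parameter set of a preset
#'
#' @param name preset name (see [experiment_presets()])
#' @param profile resolution profile
#' @return `pore_params`
#' @export
preset_params <- function(name, profile = c("coarse", "default", "fine")) {
  profile <- match.arg(profile)
  presets <- experiment_presets()
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  def <- presets[[name]]
  geom <- sim_geometry(L_p = bp_to_m(def$L_p_bp))
  pore_params(geom = geom,
              drive = drive_params(E_nom = def$E_nom, geom = geom),
              num = resolution_profile(profile))
}

#' Run an experiment preset
#'
#' Sweeps the trajectory for the preset, optionally writing the CSV (with a
#' self-describing metadata header) and a JSON-lines log into `out_dir`.
#'
#' @param name preset name
#' @param profile resolution profile
#' @param out_dir output directory, or `NULL` to skip writing
#' @param grid_bp position grid override (bp)
#' @param progress print per-position progress
#' @return `pf_trajectory` (invisibly when writing)
#' @export
run_preset <- function(name, profile = c("coarse", "default", "fine"),
                       out_dir = NULL, grid_bp = NULL, progress = FALSE) {
  params <- preset_params(name, profile)
  t0 <- proc.time()[3]
  traj <- sweep_trajectory(params, grid_bp = grid_bp, progress = progress)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(out_dir, paste0(name, "_", match.arg(profile), ".csv"))
    write_trajectory_csv(traj, csv)
    pf_log(list(preset = name, profile = match.arg(profile),
                rows = nrow(traj), converged = sum(traj$converged),
                wall_time_s = round(proc.time()[3] - t0, 1)),
           file.path(out_dir, "run_log.jsonl"))
    return(invisible(traj))
  }
  traj
}
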