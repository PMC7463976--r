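# Trajectory CSV files with self-describing metadata headers, field/mesh
# export in standard unstructured-mesh interchange formats (VTK .vtu XML and
# Gmsh .msh v2.2, both plain text), and JSON-lines run logs.

#' Write a trajectory to CSV with a metadata header
#'
#' The header lines (prefixed `#`) record every parameter needed to re-run
#' the sweep; [read_trajectory_csv()] restores both table and metadata.
#'
#' @param traj `pf_trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(traj, path) {
  meta <- attr(traj, "meta")
  params <- attr(traj, "params")
  hdr <- c(
    sprintf("# poreflow trajectory v%s", as.character(utils::packageVersion("poreflow"))),
    sprintf("# E_nom_V_per_m: %.10g", meta$E_nom),
    sprintf("# L_p_bp: %.10g", meta$L_p_bp),
    sprintf("# sigma_p_C_per_m2: %.10g", meta$sigma_p),
    sprintf("# C0_mol_per_m3: %.10g", meta$C0),
    sprintf("# mode: %s", meta$mode),
    sprintf("# bl_frac: %.10g", meta$bl_frac),
    sprintf("# h_bulk_m: %.10g", meta$h_bulk),
    sprintf("# I0_A: %.10g", attr(traj, "I0")),
    sprintf("# W_m: %.10g", params$geom$W),
    sprintf("# H_m: %.10g", params$geom$H),
    sprintf("# h_m: %.10g", params$geom$h),
    sprintf("# b_m: %.10g", params$geom$b),
    sprintf("# a_m: %.10g", params$geom$a))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(traj), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @return for the reader: a data frame with attribute `meta` (named list of
#'   the header values)
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr[-1]) {
    kv <- sub("^# ", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- if (grepl("^[-0-9.eE+]+$", val)) as.numeric(val) else val
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  attr(df, "meta") <- meta
  df
}

#' Export a solution's fields (or a bare mesh) to a VTK .vtu file
#'
#' Plain-text XML UnstructuredGrid readable by standard VTK viewers, with
#' point-data arrays phi, c1, c2, c1_minus_c2, p and the velocity vector.
#'
#' @param sol `pf_solution` (or a `pf_mesh` for a mesh-only file)
#' @param path output file (`.vtu`)
#' @return `path`, invisibly
#' @export
export_fields_vtu <- function(sol, path) {
  mesh <- if (inherits(sol, "pf_mesh")) sol else sol$mesh
  n <- nrow(mesh$p)
  m <- nrow(mesh$t)
  num <- function(x) paste(formatC(x, format = "g", digits = 17), collapse = " ")
  arrays <- character()
  if (!inherits(sol, "pf_mesh")) {
    dat <- list(phi = sol$phi, c1 = sol$conc[[1]], c2 = sol$conc[[2]],
                c1_minus_c2 = sol$conc[[1]] - sol$conc[[2]], p = sol$p)
    for (nmx in names(dat)) {
      arrays <- c(arrays, sprintf(
        '<DataArray type="Float64" Name="%s" format="ascii">%s</DataArray>',
        nmx, num(dat[[nmx]])))
    }
    uvec <- cbind(sol$vel[, 1], sol$vel[, 2], 0)
    arrays <- c(arrays, sprintf(
      '<DataArray type="Float64" Name="u" NumberOfComponents="3" format="ascii">%s</DataArray>',
      num(as.vector(t(uvec)))))
  }
  xml <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m),
    '<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    num(as.vector(t(cbind(mesh$p, 0)))),
    '</DataArray></Points>',
    '<Cells>',
    sprintf('<DataArray type="Int32" Name="connectivity" format="ascii">%s</DataArray>',
            paste(as.vector(t(mesh$t - 1L)), collapse = " ")),
    sprintf('<DataArray type="Int32" Name="offsets" format="ascii">%s</DataArray>',
            paste(seq_len(m) * 3L, collapse = " ")),
    sprintf('<DataArray type="UInt8" Name="types" format="ascii">%s</DataArray>',
            paste(rep(5L, m), collapse = " ")),
    '</Cells>',
    if (length(arrays)) c('<PointData>', arrays, '</PointData>') else character(),
    '</Piece></UnstructuredGrid></VTKFile>')
  writeLines(unlist(xml), path)
  invisible(path)
}

#' Read back a .vtu file written by [export_fields_vtu()]
#'
#' Minimal reader for round-trip checks: returns points, triangles and the
#' named point-data arrays.
#'
#' @param path `.vtu` file
#' @return list: `p`, `t`, `data` (named list)
#' @export
read_fields_vtu <- function(path) {
  txt <- paste(readLines(path), collapse = "\n")
  grab <- function(pattern) {
    mm <- regmatches(txt, regexec(pattern, txt))[[1]]
    as.numeric(strsplit(trimws(mm[2]), "\\s+")[[1]])
  }
  pts <- grab('<Points><DataArray[^>]*>([^<]*)</DataArray>')
  p <- matrix(pts, ncol = 3, byrow = TRUE)[, 1:2, drop = FALSE]
  conn <- grab('Name="connectivity"[^>]*>([^<]*)<')
  t <- matrix(as.integer(conn) + 1L, ncol = 3, byrow = TRUE)
  data <- list()
  mm <- gregexpr('<DataArray type="Float64" Name="([^"]+)"( NumberOfComponents="3")? format="ascii">([^<]*)</DataArray>', txt)
  hits <- regmatches(txt, mm)[[1]]
  for (h in hits) {
    nm <- sub('.*Name="([^"]+)".*', "\\1", h)
    if (nm %in% c("connectivity", "offsets", "types")) next
    vals <- as.numeric(strsplit(trimws(sub(".*>([^<]*)<.*", "\\1", h)), "\\s+")[[1]])
    data[[nm]] <- vals
  }
  list(p = p, t = t, data = data)
}

#' Export a mesh to Gmsh .msh (version 2.2, ASCII)
#'
#' Boundary edges are written as 2-node line elements whose physical tag is
#' the boundary group; triangles carry physical tag 0.
#'
#' @param mesh `pf_mesh`
#' @param path output file (`.msh`)
#' @return `path`, invisibly
#' @export
export_mesh_msh <- function(mesh, path) {
  n <- nrow(mesh$p)
  m <- nrow(mesh$t)
  k <- nrow(mesh$be)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(n)), con)
  writeLines(sprintf("%d %.17g %.17g 0", seq_len(n), mesh$p[, 1], mesh$p[, 2]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(m + k)), con)
  writeLines(sprintf("%d 1 2 %d %d %d %d", seq_len(k), mesh$be_tag,
                     mesh$be_tag, mesh$be[, 1], mesh$be[, 2]), con)
  writeLines(sprintf("%d 2 2 0 0 %d %d %d", k + seq_len(m),
                     mesh$t[, 1], mesh$t[, 2], mesh$t[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Append a JSON-lines record to a run log
#'
#' @param record named list
#' @param path log file (created if missing)
#' @return `path`, invisibly
#' @export
pf_log <- function(record, path) {
  line <- jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
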