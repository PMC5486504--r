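# Deterministic VTK legacy ASCII writers (fixed float precision) for
# visualization of masks, fields and wall scalars.

vtk_num <- function(x) formatC(x, format = "e", digits = 8)

#' Write the mesh mask as a VTK structured-points file
#'
#' Legacy ASCII `STRUCTURED_POINTS` with the fluid mask as a scalar
#' (1 fluid, 0 solid). Deterministic output for fixed inputs.
#'
#' @param mesh An `aneurysm_mesh`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_vtk_mask <- function(mesh, path) {
  stopifnot(inherits(mesh, "aneurysm_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "aneuflow fluid mask", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", mesh$nx, mesh$ny),
               sprintf("ORIGIN %s %s 0", vtk_num(mesh$cell_size / 2),
                       vtk_num(mesh$cell_size / 2)),
               sprintf("SPACING %s %s 1", vtk_num(mesh$cell_size),
                       vtk_num(mesh$cell_size)),
               sprintf("POINT_DATA %d", mesh$nx * mesh$ny),
               "SCALARS fluid_mask int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(as.vector(mesh$fluid))), con)
  invisible(path)
}

#' Write a flow-field snapshot as a VTK structured-points file
#'
#' Cell-centered velocity vectors (face velocities averaged to centers) and
#' pressure scalars for one saved time step.
#'
#' @param field A `flow_field`.
#' @param step Time index within the saved cycle.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_vtk_field <- function(field, step, path) {
  stopifnot(inherits(field, "flow_field"))
  nx <- field$nx; ny <- field$ny
  u <- field$u[, , step]
  v <- field$v[, , step]
  p <- field$p[, , step]
  uc <- 0.5 * (u[1:nx, ] + u[2:(nx + 1), ])
  vc <- 0.5 * (v[, 1:ny] + v[, 2:(ny + 1)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("aneuflow flow field t=%s s", vtk_num(field$times[step])),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %s %s 0", vtk_num(field$cell_size / 2),
                       vtk_num(field$cell_size / 2)),
               sprintf("SPACING %s %s 1", vtk_num(field$cell_size),
                       vtk_num(field$cell_size)),
               sprintf("POINT_DATA %d", nx * ny),
               "VECTORS velocity float"), con)
  writeLines(paste(vtk_num(as.vector(uc)), vtk_num(as.vector(vc)), "0"), con)
  writeLines(c("SCALARS pressure float 1", "LOOKUP_TABLE default"), con)
  writeLines(vtk_num(as.vector(p)), con)
  invisible(path)
}

#' Write wall elements with time-averaged WSS as VTK polydata
#'
#' Wall-element face centers as points carrying the time-averaged WSS
#' scalar and an integer region tag (0 other, 1 sac, 2 parent probe).
#'
#' @param series A `wall_shear_series` with `time_averaged` present.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_vtk_wall <- function(series, path) {
  stopifnot(inherits(series, "wall_shear_series"))
  if (is.null(series$time_averaged)) series <- time_average_wss(series)
  el <- series$elements
  n <- nrow(el)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "aneuflow wall shear (time-averaged)", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(paste(vtk_num(el$x), vtk_num(el$y), "0"), con)
  writeLines(c(sprintf("POINT_DATA %d", n),
               "SCALARS wss_time_avg float 1",
               "LOOKUP_TABLE default"), con)
  writeLines(vtk_num(series$time_averaged), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  region_code <- c(other = 0L, sac = 1L, parent_probe = 2L)
  writeLines(as.character(region_code[el$region]), con)
  invisible(path)
}
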