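#' Write a mesh and fields to a legacy VTK unstructured-grid file
#'
#' ASCII legacy VTK (DATASET UNSTRUCTURED_GRID, cell type 10 = tetrahedron)
#' for visualization in ParaView and friends. Nodal displacements can be
#' applied with a display scale factor to export deformed shapes.
#'
#' @param mesh a `fem_mesh`.
#' @param path output file.
#' @param point_data named list of per-node scalars (length n vectors).
#' @param cell_data named list of per-element scalars.
#' @param displacements optional n x 3 matrix added to the coordinates.
#' @param scale display scale factor for `displacements` (default 1; the
#'   animation convention elsewhere in the package is 20x).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, point_data = list(), cell_data = list(),
                      displacements = NULL, scale = 1) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  xyz <- mesh$nodes
  if (!is.null(displacements)) xyz <- xyz + scale * displacements
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "mandfix export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g", xyz[, 1], xyz[, 2], xyz[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1] - 1L,
                     mesh$tets[, 2] - 1L, mesh$tets[, 3] - 1L,
                     mesh$tets[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", point_data[[nm]]), con)
    }
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", cell_data[[nm]]), con)
    }
  }
  invisible(path)
}
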