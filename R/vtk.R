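# VTK legacy structured-grid ASCII output for field inspection.

#' Write nodal fields as a VTK legacy structured grid
#'
#' ASCII `STRUCTURED_GRID` file with one `SCALARS` array per entry of
#' `point_data` (values in mesh node order, i fastest).
#'
#' @param path output file; `mesh` a `bs_mesh`.
#' @param point_data named list of numeric vectors (length = node count).
#' @export
write_vtk_structured <- function(path, mesh, point_data = list()) {
  N <- nrow(mesh$nodes)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "biosensim channel fields",
               "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", mesh$nx, mesh$ny),
               sprintf("POINTS %d double", N)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", N), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (length(v) != N) stop(sprintf("field '%s' has wrong length", nm))
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.12g", v), con)
    }
  }
  invisible(path)
}
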