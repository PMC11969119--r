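# Mesh and field export: Gmsh MSH 2.2 and legacy VTK writers.

#' Export a mesh in Gmsh MSH 2.2 format
#'
#' Boundary edges are written as 2-node line elements whose physical tag
#' encodes the boundary kind (1 inlet, 2 ICA outlet, 3 ECA outlet, 10
#' wall); triangles carry physical tag 100.
#'
#' @param mesh A `mesh2d`.
#' @param path Output file path.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  n <- nrow(mesh$nodes)
  writeLines(c("$Nodes", as.character(n)), con)
  writeLines(sprintf("%d %.12g %.12g 0", seq_len(n),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines("$EndNodes", con)
  be <- mesh$boundary_edges
  tagmap <- c(INLET = 1L, OUTLET_ICA = 2L, OUTLET_ECA = 3L, WALL = 10L)
  m <- nrow(mesh$triangles)
  writeLines(c("$Elements", as.character(nrow(be) + m)), con)
  writeLines(sprintf("%d 1 2 %d %d %d %d", seq_len(nrow(be)),
                     tagmap[be$tag], tagmap[be$tag], be$n1, be$n2), con)
  writeLines(sprintf("%d 2 2 100 100 %d %d %d", nrow(be) + seq_len(m),
                     mesh$triangles[, 1], mesh$triangles[, 2],
                     mesh$triangles[, 3]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Export a mesh (and optional nodal fields) as legacy VTK
#'
#' @param mesh A `mesh2d`.
#' @param path Output file path.
#' @param point_data Optional named list of per-node numeric vectors
#'   (scalars) or two-column matrices (vectors).
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  writeLines(c("# vtk DataFile Version 3.0", "carotidflow mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.12g %.12g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1,
                     mesh$triangles[, 2] - 1, mesh$triangles[, 3] - 1), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (!is.null(point_data) && length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 2) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.10g %.10g 0", v[, 1], v[, 2]), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10g", as.numeric(v)), con)
      }
    }
  }
  invisible(path)
}

#' Export a flow field as a legacy-VTK time series
#'
#' Writes one `.vtk` file per stored instant (velocity, pressure) plus a
#' JSON index with the instant times.
#'
#' @param field A `flow_field`.
#' @param dir Output directory.
#' @param basename File name stem.
#' @return Invisibly, the index path.
#' @export
write_field_series <- function(field, dir, basename = "field") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(field$times))
  for (k in seq_along(field$times)) {
    files[k] <- file.path(dir, sprintf("%s_%03d.vtk", basename, k))
    write_mesh_vtk(field$mesh, files[k],
                   point_data = list(
                     velocity = cbind(field$ux[, k], field$uy[, k]),
                     pressure = field$p[, k]))
  }
  idx <- file.path(dir, paste0(basename, "_series.json"))
  jsonlite::write_json(list(times = field$times, files = basename(files)),
                       idx, auto_unbox = TRUE, digits = NA)
  invisible(idx)
}
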