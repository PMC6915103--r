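# Plain-text exporters: VTK XML unstructured grids (VTU), Gmsh MSH 4.1,
# VTK legacy polylines, and per-fiber / curve CSVs. ASCII only; these files
# are meant for inspection in ParaView/Gmsh, not as an interchange layer.

#' Write a volume mesh (optionally with fields) as ASCII VTU
#'
#' Cell data always include the integer `compartment` label; nodal fields
#' (e.g. `V_volts`) can be attached as point data.
#'
#' @param mesh a `volume_mesh`.
#' @param path output file path (`.vtu`).
#' @param point_data named list of per-node numeric vectors.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w(sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1L, function(r) paste(r, collapse = " ")), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$tets - 1L, 1L, function(r) paste(r, collapse = " ")), con)
  w('        </DataArray>')
  w('        <DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(m) * 4L), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("10", m), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('      <CellData Scalars="compartment">')
  w('        <DataArray type="Int32" Name="compartment" format="ascii">')
  writeLines(paste(mesh$label), con)
  w('        </DataArray>')
  w('      </CellData>')
  if (length(point_data)) {
    w('      <PointData>')
    for (nm in names(point_data)) {
      w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm))
      writeLines(paste(point_data[[nm]]), con)
      w('        </DataArray>')
    }
    w('      </PointData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Write a volume mesh as Gmsh MSH 4.1 (ASCII)
#'
#' One volume entity per compartment; element labels map to entity tags.
#'
#' @param mesh a `volume_mesh`.
#' @param path output file path (`.msh`).
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path) {
  n <- nrow(mesh$nodes)
  labs <- sort(unique(mesh$label))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$Entities")
  w(sprintf("0 0 0 %d", length(labs)))
  for (l in labs) w(sprintf("%d -1e9 -1e9 -1e9 1e9 1e9 1e9 1 %d 0", l, l))
  w("$EndEntities")
  w("$Nodes")
  # single block on the first volume entity
  w(sprintf("1 %d 1 %d", n, n))
  w(sprintf("3 %d 0 %d", labs[1L], n))
  writeLines(paste(seq_len(n)), con)
  writeLines(apply(mesh$nodes, 1L, function(r) paste(r, collapse = " ")), con)
  w("$EndNodes")
  w("$Elements")
  m <- nrow(mesh$tets)
  w(sprintf("%d %d 1 %d", length(labs), m, m))
  eid <- 0L
  for (l in labs) {
    rows <- which(mesh$label == l)
    w(sprintf("3 %d 4 %d", l, length(rows)))
    block <- cbind(eid + seq_along(rows), mesh$tets[rows, , drop = FALSE])
    writeLines(apply(block, 1L, function(r) paste(r, collapse = " ")), con)
    eid <- eid + length(rows)
  }
  w("$EndElements")
  invisible(path)
}

#' Write fibers as VTK legacy polylines
#'
#' @param fibers list of `fiber_path` objects.
#' @param path output file path (`.vtk`).
#' @return `path`, invisibly.
#' @export
write_fibers_vtk <- function(fibers, path) {
  pts <- do.call(rbind, lapply(fibers, `[[`, "points"))
  counts <- vapply(fibers, function(f) nrow(f$points), 1L)
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("auditory nerve fiber trajectories (mm)")
  w("ASCII")
  w("DATASET POLYDATA")
  w(sprintf("POINTS %d double", nrow(pts)))
  writeLines(apply(pts, 1L, function(r) paste(r, collapse = " ")), con)
  w(sprintf("LINES %d %d", length(fibers), length(fibers) + sum(counts)))
  for (i in seq_along(fibers)) {
    w(paste(c(counts[i], offsets[i] + seq_len(counts[i]) - 1L), collapse = " "))
  }
  invisible(path)
}

#' Write one fiber (or curve) as CSV
#'
#' Columns: `s_mm, x, y, z` and, for soma-annotated fibers, `region`.
#'
#' @param fiber a `fiber_path` or an n x 3 coordinate matrix.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fiber_csv <- function(fiber, path) {
  if (inherits(fiber, "fiber_path")) {
    df <- data.frame(s_mm = fiber$s, x = fiber$points[, 1L],
                     y = fiber$points[, 2L], z = fiber$points[, 3L])
    if (!is.null(fiber$region)) df$region <- fiber$region
  } else {
    df <- data.frame(s_mm = polyline_arclength(fiber), x = fiber[, 1L],
                     y = fiber[, 2L], z = fiber[, 3L])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an activation profile as CSV
#'
#' @param profile an `activation_profile`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
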