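#' Write a triangle shell mesh as a legacy-VTK unstructured grid
#'
#' ASCII legacy VTK with full double precision (`%.17g`), so coordinates
#' survive a write/read round trip bitwise. Optional per-point vector fields
#' (e.g. mode shapes) are attached as `POINT_DATA` vectors.
#'
#' @param mesh A [gv_mesh()] (or list with `nodes`, `tris`).
#' @param path Output file path.
#' @param point_vectors Named list of n x 3 matrices to attach.
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(mesh, path, point_vectors = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tris)
  writeLines(c("# vtk DataFile Version 3.0",
               "gvbuckle shell mesh",
               "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$tris[, 1] - 1L, mesh$tris[, 2] - 1L,
                     mesh$tris[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (!is.null(point_vectors) && length(point_vectors)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_vectors)) {
      v <- point_vectors[[nm]]
      stopifnot(nrow(v) == n, ncol(v) == 3)
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
    }
  }
  invisible(path)
}

#' Read a legacy-VTK triangle mesh written by [write_vtk()]
#'
#' @param path File path.
#' @return List with `nodes` (n x 3), `tris` (m x 3, 1-based) and any point
#'   vector fields under `point_vectors`.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS ", lines)[1]
  n <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  pts <- scan(text = lines[(ip + 1):(ip + n)], quiet = TRUE)
  nodes <- matrix(pts, ncol = 3, byrow = TRUE)
  ic <- grep("^CELLS ", lines)[1]
  m <- as.integer(strsplit(lines[ic], " ")[[1]][2])
  cells <- scan(text = lines[(ic + 1):(ic + m)], quiet = TRUE)
  cells <- matrix(cells, ncol = 4, byrow = TRUE)
  if (any(cells[, 1] != 3)) stop("non-triangle cells in VTK file")
  tris <- cells[, 2:4, drop = FALSE] + 1L
  storage.mode(tris) <- "integer"
  out <- list(nodes = nodes, tris = tris)
  iv <- grep("^VECTORS ", lines)
  if (length(iv)) {
    pv <- list()
    for (i in iv) {
      nm <- strsplit(lines[i], " ")[[1]][2]
      vals <- scan(text = lines[(i + 1):(i + n)], quiet = TRUE)
      pv[[nm]] <- matrix(vals, ncol = 3, byrow = TRUE)
    }
    out$point_vectors <- pv
  }
  out
}
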