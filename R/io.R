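#' Write a mesh as OFF
#'
#' @param mesh a [spine_mesh()].
#' @param path output file.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mesh from OFF
#'
#' @param path input file.
#' @param fixed optional fixed vertex ids to attach.
#' @return a [spine_mesh()].
#' @export
read_off <- function(path, fixed = integer(0)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  stopifnot(trimws(lines[1]) == "OFF")
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]
  nf <- counts[2]
  vtx <- do.call(rbind, lapply(lines[2 + seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(lines[2 + nv + seq_len(nf)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    stopifnot(x[1] == 3)
    x[2:4] + 1L
  }))
  spine_mesh(vtx, fc, fixed = fixed)
}

#' Write a mesh as ASCII PLY
#'
#' @param mesh a [spine_mesh()].
#' @param path output file.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY mesh
#'
#' @param path input file.
#' @param fixed optional fixed vertex ids.
#' @return a [spine_mesh()].
#' @export
read_ply <- function(path, fixed = integer(0)) {
  lines <- readLines(path)
  stopifnot(trimws(lines[1]) == "ply")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vtx <- do.call(rbind, lapply(lines[hdr_end + seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(lines[hdr_end + nv + seq_len(nf)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    x[2:4] + 1L
  }))
  spine_mesh(vtx, fc, fixed = fixed)
}

#' Write a mesh as legacy VTK polydata (ASCII)
#'
#' For time-stamped mesh series visualization.
#'
#' @param mesh a [spine_mesh()].
#' @param path output file.
#' @param point_data optional named list of per-vertex numeric vectors.
#' @export
write_vtk_polydata <- function(mesh, path, point_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  writeLines(c("# vtk DataFile Version 3.0", "spine membrane", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nf, 4 * nf), con)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 10), con)
    }
  }
  invisible(path)
}

#' Write lattice fields as legacy VTK structured points (ASCII)
#'
#' @param grid a [lattice_grid()].
#' @param fields named list of arrays with dim equal to the grid shape.
#' @param path output file.
#' @export
write_vtk_image <- function(grid, fields, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "lattice fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$shape[1], grid$shape[2],
                       grid$shape[3]),
               sprintf("ORIGIN %g %g %g", grid$origin[1], grid$origin[2],
                       grid$origin[3]),
               sprintf("SPACING %g %g %g", grid$spacing, grid$spacing,
                       grid$spacing),
               sprintf("POINT_DATA %d", prod(grid$shape))), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(as.numeric(fields[[nm]]), digits = 10), con)
  }
  invisible(path)
}
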