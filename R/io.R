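#' Export particle positions as XYZ
#'
#' Plain XYZ with an element/label column, suitable for per-frame
#' trajectory output (append frames to the same connection for a
#' multi-frame file).
#'
#' @param pos n x 3 matrix of positions.
#' @param path output file.
#' @param labels per-particle labels (e.g. \code{"fluid"},
#'   \code{"body"}, \code{"backbone"}, \code{"auxiliary"}).
#' @param comment second-line comment.
#' @param append append a frame instead of overwriting.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(pos, path, labels = rep("P", nrow(pos)),
                      comment = "", append = FALSE) {
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(as.character(nrow(pos)), con)
  writeLines(comment, con)
  writeLines(sprintf("%s %.8g %.8g %.8g", labels, pos[, 1], pos[, 2],
                     pos[, 3]), con)
  invisible(path)
}

#' Export a triangulated mesh as legacy VTK polydata or OFF
#'
#' @param mesh a \code{tri_mesh}.
#' @param path output file.
#' @param positions optional vertex positions.
#' @return \code{path}, invisibly.
#' @export
write_vtk <- function(mesh, path, positions = mesh$vertices) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(positions)
  nt <- nrow(mesh$faces)
  writeLines(c("# vtk DataFile Version 3.0", "tri_mesh", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nv)), con)
  writeLines(sprintf("%.8g %.8g %.8g", positions[, 1], positions[, 2],
                     positions[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nt, 4 * nt), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_vtk
#' @export
write_off <- function(mesh, path, positions = mesh$vertices) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(positions), nrow(mesh$faces)), con)
  writeLines(sprintf("%.8g %.8g %.8g", positions[, 1], positions[, 2],
                     positions[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Export a flagellum chain as labelled XYZ
#' @param chain a \code{flagellum_chain}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_flagellum_xyz <- function(chain, path) {
  labels <- c(rep("backbone", chain$Ns + 1L), rep("auxiliary", 4L * chain$Ns))
  write_xyz(chain$pos, path, labels,
            comment = sprintf("Ns=%d state=%s", chain$Ns, chain$state))
}

#' Write an observable series as tab-delimited text
#' @param series an [observable_series()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_observables <- function(series, path) {
  utils::write.table(series, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
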