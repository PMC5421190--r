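#' Write a mesh with a per-vertex scalar to ASCII PLY
#'
#' Minimal ASCII PLY export (vertex positions plus one scalar property,
#' triangle faces), readable by standard mesh viewers.
#'
#' @param mesh A [build_icosphere()] mesh.
#' @param field Numeric vector over vertices.
#' @param path Output file path.
#' @param property Name of the scalar property.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, field, path, property = "value") {
  stopifnot(inherits(mesh, "sphere_mesh"),
            length(field) == nrow(mesh$vertices))
  V <- nrow(mesh$vertices)
  F_ <- nrow(mesh$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", V),
               "property float x", "property float y", "property float z",
               paste("property float", property),
               paste("element face", F_),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.8g %.8g %.8g %.8g",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3], field), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$triangles[, 1] - 1L, mesh$triangles[, 2] - 1L,
                     mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' Export animation frames of a planform oscillation
#'
#' Evaluates the planform over one period at `n_frames` equally spaced
#' times and writes numbered PLY exports.
#'
#' @param pf A `planform_field` from [synthesize_planform()].
#' @param mesh The mesh whose vertices the field was evaluated on.
#' @param dir Output directory.
#' @param n_frames Number of frames over one period.
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
planform_frames <- function(pf, mesh, dir, n_frames = 8L, prefix = "frame") {
  stopifnot(inherits(pf, "planform_field"), inherits(mesh, "sphere_mesh"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  period <- 2 * pi / pf$omega
  ts <- seq(0, period, length.out = n_frames + 1L)[seq_len(n_frames)]
  paths <- vapply(seq_along(ts), function(i) {
    p <- file.path(dir, sprintf("%s_%03d.ply", prefix, i))
    write_ply(mesh, pf$field_fun(ts[i], mesh$vertices), p)
    p
  }, character(1))
  invisible(paths)
}

#' Export a planform field as a (theta, phi, value) table
#'
#' @param pf A `planform_field` from [synthesize_planform()].
#' @param path Optional CSV path; if `NULL` the data frame is returned.
#' @return Data frame (invisibly when written).
#' @export
planform_to_csv <- function(pf, path = NULL) {
  stopifnot(inherits(pf, "planform_field"))
  p <- pf$points
  df <- data.frame(theta = acos(clamp_cosine(p[, 3])),
                   phi = atan2(p[, 2], p[, 1]) %% (2 * pi),
                   value = pf$values)
  if (is.null(path)) return(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
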