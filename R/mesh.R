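#' Triangulated icosphere mesh with quadrature weights
#'
#' Builds a geodesic sphere by recursive quadrisection of the icosahedron,
#' projecting every new vertex onto the unit sphere. Level \eqn{k} has
#' \eqn{F = 20 \cdot 4^k} triangles and \eqn{V = 10 \cdot 4^k + 2} vertices
#' (Euler characteristic 2). Quadrature weights discretize the surface
#' integral: each vertex receives one third of the spherical areas
#' (spherical excess, l'Huilier's formula) of its incident triangles, and
#' the weights are then rescaled so that they sum to \eqn{4\pi} exactly.
#'
#' @param level Subdivision level, integer in `0:7` (the cap guards
#'   against accidental huge meshes).
#' @return Object of class `sphere_mesh`: `vertices` (V x 3 unit vectors),
#'   `triangles` (F x 3 vertex indices), `weights` (length V, summing to
#'   \eqn{4\pi}), `areas` (per triangle), `level`, and the pre-normalization
#'   total area `raw_area`.
#' @export
build_icosphere <- function(level) {
  if (length(level) != 1L || level < 0 || level > 7 || level != round(level)) {
    stop("'level' must be an integer in 0..7")
  }
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(level)) {
    nv <- nrow(v)
    edge_key <- new.env(parent = emptyenv(), hash = TRUE)
    verts <- vector("list", 0)
    midpoint <- function(i, j) {
      key <- paste0(min(i, j), "_", max(i, j))
      id <- edge_key[[key]]
      if (is.null(id)) {
        m <- v[i, ] + v[j, ]
        m <- m / sqrt(sum(m^2))
        verts[[length(verts) + 1L]] <<- m
        id <- nv + length(verts)
        edge_key[[key]] <- id
      }
      id
    }
    nf <- matrix(0L, 4L * nrow(f), 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(4L * t - 3L):(4L * t), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                            c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, verts))
    f <- nf
  }
  areas <- spherical_triangle_areas(v, f)
  if (any(areas <= 0)) stop("degenerate triangle in icosphere construction")
  w <- numeric(nrow(v))
  third <- rep(areas / 3, 3L)
  idx <- as.vector(f)
  w <- as.vector(tapply(third, factor(idx, levels = seq_len(nrow(v))), sum))
  raw <- sum(w)
  w <- w * (4 * pi / raw)
  structure(list(vertices = v, triangles = f, weights = w, areas = areas,
                 level = as.integer(level), raw_area = raw),
            class = "sphere_mesh") -> mesh
  attr(mesh, "harmonics_cache") <- new.env(parent = emptyenv())
  mesh
}

# spherical triangle areas via l'Huilier's spherical-excess formula
spherical_triangle_areas <- function(v, f) {
  dotc <- function(i, j) clamp_cosine(rowSums(v[f[, i], , drop = FALSE] *
                                                v[f[, j], , drop = FALSE]))
  a <- acos(dotc(2, 3))
  b <- acos(dotc(1, 3))
  cc <- acos(dotc(1, 2))
  s <- (a + b + cc) / 2
  t <- sqrt(pmax(0, tan(s / 2) * tan((s - a) / 2) * tan((s - b) / 2) *
                   tan((s - cc) / 2)))
  4 * atan(t)
}

#' @export
print.sphere_mesh <- function(x, ...) {
  V <- nrow(x$vertices); F_ <- nrow(x$triangles)
  E <- V + F_ - 2
  cat(sprintf("icosphere level %d: %d vertices, %d triangles, %d edges (chi = %d)\n",
              x$level, V, F_, E, V - E + F_))
  cat(sprintf("quadrature: sum(w) = %.12f (4*pi = %.12f), raw area %.6f\n",
              sum(x$weights), 4 * pi, x$raw_area))
  invisible(x)
}

#' Center of mass of a scalar field on the sphere
#'
#' The first moment \eqn{m = \sum_i w_i u(r_i) r_i \in \mathbb{R}^3}. For a
#' homogeneous field it vanishes by symmetry; its trajectory distinguishes
#' standing oscillations (near-linear segments through the origin) from
#' rotating waves (circular orbits).
#'
#' @param field Numeric vector over mesh vertices.
#' @param mesh A [build_icosphere()] mesh.
#' @return Numeric length-3 vector.
#' @export
center_of_mass <- function(field, mesh) {
  stopifnot(inherits(mesh, "sphere_mesh"),
            length(field) == nrow(mesh$vertices))
  as.vector(crossprod(mesh$vertices, mesh$weights * field))
}
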