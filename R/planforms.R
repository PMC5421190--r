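#' Catalog of C-axial isotropy branches
#'
#' At a dynamic (Hopf) instability of the spherical harmonics of degree
#' \eqn{n_c}, the equivariant Hopf theorem guarantees one branch of periodic
#' solutions for every C-axial isotropy subgroup of \eqn{O(3) \times S^1}
#' acting on \eqn{V_{n_c} \oplus V_{n_c}}. The catalog for
#' \eqn{1 \le n_c \le 6} is transcribed as static data: each branch records
#' the subgroup data \eqn{H = J \times Z_2^c}, the spatial kernel
#' \eqn{K = \ker\theta} and the image of the twist homomorphism
#' \eqn{\theta(H)}. A branch is a travelling wave iff
#' \eqn{\theta(H) = S^1} (its spatial pattern rotates rigidly); all other
#' branches are standing waves. For \eqn{n_c = 4} the representative
#' fixed-point vectors are included (indexed \eqn{m = -4, \dots, 4}), with
#' the octahedral and tetrahedral entries carrying the square-root ratios
#' \eqn{(\sqrt5, \sqrt{14}, \sqrt5)} and
#' \eqn{(\sqrt7, \sqrt{12}i, -\sqrt{10}, \sqrt{12}i, \sqrt7)} required for
#' invariance under the three-fold axes (verified by
#' [check_spatiotemporal_symmetry()]).
#'
#' @param nc Critical degree, integer in `1:6`.
#' @return A list of `isotropy_branch` objects (fields `nc`, `name`,
#'   `J_name`, `K_name`, `theta_image`, `wave_type`, `fix_vector` (complex
#'   length `2*nc+1` or `NULL`), `generators`).
#' @export
branches_for_degree <- function(nc) {
  if (length(nc) != 1L || !(nc %in% 1:6)) {
    stop("the catalog covers critical degrees 1..6")
  }
  rows <- planform_catalog[[nc]]
  lapply(rows, function(r) structure(r, class = "isotropy_branch"))
}

#' @export
print.isotropy_branch <- function(x, ...) {
  cat(sprintf("branch %-10s (nc=%d): J=%s K=%s theta(H)=%s [%s]\n",
              x$name, x$nc, x$J_name, x$K_name, x$theta_image, x$wave_type))
  invisible(x)
}

# -- catalog data ----------------------------------------------------------

branch_row <- function(nc, name, J, K, theta, fix = NULL, generators = NULL) {
  list(nc = as.integer(nc), name = name, J_name = J, K_name = K,
       theta_image = theta,
       wave_type = if (identical(theta, "S1")) "travelling" else "standing",
       fix_vector = fix, generators = generators)
}

# unit vector with 1 at order m (degree nc), positions m = -nc..nc
fix_unit <- function(nc, m) {
  v <- rep(0 + 0i, 2 * nc + 1)
  v[m + nc + 1L] <- 1
  v
}

# generator helpers: a generator is list(gamma = 3x3 matrix, phase = fraction
# of the period shifted by the twist)
gen <- function(gamma, phase = 0) list(gamma = gamma, phase = phase)

#' Elementary symmetry transformations
#'
#' Rotation matrices about the z and x axes, about an arbitrary axis, and
#' the inversion \eqn{-I} (which acts on degree-\eqn{n} harmonics as
#' \eqn{(-1)^n}).
#'
#' @param angle Rotation angle in radians.
#' @param axis Length-3 axis vector (normalized internally).
#' @return 3x3 orthogonal matrix.
#' @export
rot_z <- function(angle) {
  rbind(c(cos(angle), -sin(angle), 0), c(sin(angle), cos(angle), 0), c(0, 0, 1))
}

#' @rdname rot_z
#' @export
rot_x <- function(angle) {
  rbind(c(1, 0, 0), c(0, cos(angle), -sin(angle)), c(0, sin(angle), cos(angle)))
}

#' @rdname rot_z
#' @export
rot_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' @rdname rot_z
#' @export
inversion <- function() -diag(3)

make_catalog <- function() {
  perm3 <- rot_axis(c(1, 1, 1), 2 * pi / 3)  # cyclic x -> y -> z -> x
  so2_gens <- function(k) {
    # travelling wave from a single harmonic of order -k: rotation by phi
    # about z pairs with the time shift that advances the phase k*phi
    list(gen(rot_z(2 * pi / max(k, 1)), 0),
         gen(rot_z(pi / 5), k * (pi / 5) / (2 * pi)),
         gen(inversion(), 0))
  }
  dihedral_gens <- function(k, axis_azimuth) {
    # D_{2k}~: rotation by pi/k twists by half a period, rotation by 2*pi/k
    # and the horizontal pi-rotation are spatial
    list(gen(rot_z(2 * pi / k), 0),
         gen(rot_z(pi / k), 1 / 2),
         gen(rot_z(axis_azimuth) %*% rot_x(pi) %*% rot_z(-axis_azimuth), 0),
         gen(inversion(), 0))
  }
  nc4 <- list(
    branch_row(4, "O(2)~", "O(2)", "O(2)xZ2c", "1",
               fix = fix_unit(4, 0),
               generators = list(gen(rot_z(0.7349), 0), gen(rot_x(pi), 0),
                                 gen(inversion(), 0))),
    branch_row(4, "O~", "O", "OxZ2c", "1",
               fix = sqrt(5) * fix_unit(4, -4) + sqrt(14) * fix_unit(4, 0) +
                 sqrt(5) * fix_unit(4, 4),
               generators = list(gen(rot_z(pi / 2), 0), gen(perm3, 0),
                                 gen(rot_x(pi), 0), gen(inversion(), 0))),
    branch_row(4, "T~", "T", "D2xZ2c", "Z3",
               fix = sqrt(7) * fix_unit(4, -4) + sqrt(12) * 1i * fix_unit(4, -2) -
                 sqrt(10) * fix_unit(4, 0) + sqrt(12) * 1i * fix_unit(4, 2) +
                 sqrt(7) * fix_unit(4, 4),
               generators = list(gen(rot_z(pi), 0), gen(rot_x(pi), 0),
                                 gen(perm3, 2 / 3), gen(inversion(), 0))),
    branch_row(4, "D8~", "D8", "D4xZ2c", "Z2",
               fix = fix_unit(4, -4) + fix_unit(4, 4),
               generators = dihedral_gens(4, 0)),
    branch_row(4, "D6~", "D6", "D3xZ2c", "Z2",
               fix = fix_unit(4, -3) + fix_unit(4, 3),
               generators = dihedral_gens(3, 0)),
    branch_row(4, "D4~", "D4", "D2xZ2c", "Z2",
               fix = fix_unit(4, -2) + fix_unit(4, 2),
               generators = dihedral_gens(2, 0)),
    branch_row(4, "SO(2)4~", "SO(2)", "Z4xZ2c", "S1",
               fix = fix_unit(4, -4), generators = so2_gens(4)),
    branch_row(4, "SO(2)3~", "SO(2)", "Z3xZ2c", "S1",
               fix = fix_unit(4, -3), generators = so2_gens(3)),
    branch_row(4, "SO(2)2~", "SO(2)", "Z2xZ2c", "S1",
               fix = fix_unit(4, -2), generators = so2_gens(2)),
    branch_row(4, "SO(2)1~", "SO(2)", "Z2c", "S1",
               fix = fix_unit(4, -1), generators = so2_gens(1)))
  list(
    # nc = 1
    list(branch_row(1, "O(2)~", "O(2)", "O(2)-", "Z2"),
         branch_row(1, "SO(2)1~", "SO(2)", "Z2-", "S1", fix = fix_unit(1, -1))),
    # nc = 2
    list(branch_row(2, "O(2)~", "O(2)", "O(2)xZ2c", "1", fix = fix_unit(2, 0)),
         branch_row(2, "SO(2)1~", "SO(2)", "Z2xZ2c", "S1", fix = fix_unit(2, -1)),
         branch_row(2, "SO(2)2~", "SO(2)", "Z2c", "S1", fix = fix_unit(2, -2)),
         branch_row(2, "T~", "T", "D2xZ2c", "Z3"),
         branch_row(2, "D4~", "D4", "D2xZ2c", "Z2", fix = fix_unit(2, -2) + fix_unit(2, 2))),
    # nc = 3
    list(branch_row(3, "O(2)~", "O(2)", "O(2)-", "Z2"),
         branch_row(3, "SO(2)1~", "SO(2)", "Z2-", "S1", fix = fix_unit(3, -1)),
         branch_row(3, "SO(2)2~", "SO(2)", "Z4-", "S1", fix = fix_unit(3, -2)),
         branch_row(3, "SO(2)3~", "SO(2)", "Z6-", "S1", fix = fix_unit(3, -3)),
         branch_row(3, "O~", "O", "O-", "Z2"),
         branch_row(3, "D6~", "D6", "D6d", "Z2")),
    # nc = 4 (full fix vectors and generators)
    nc4,
    # nc = 5
    list(branch_row(5, "O(2)~", "O(2)", "O(2)-", "Z2"),
         branch_row(5, "SO(2)1~", "SO(2)", "Z2-", "S1", fix = fix_unit(5, -1)),
         branch_row(5, "SO(2)2~", "SO(2)", "Z4-", "S1", fix = fix_unit(5, -2)),
         branch_row(5, "SO(2)3~", "SO(2)", "Z6-", "S1", fix = fix_unit(5, -3)),
         branch_row(5, "SO(2)4~", "SO(2)", "Z8-", "S1", fix = fix_unit(5, -4)),
         branch_row(5, "SO(2)5~", "SO(2)", "Z10-", "S1", fix = fix_unit(5, -5)),
         branch_row(5, "T~", "T", "D2", "Z6"),
         branch_row(5, "D10~", "D10", "D10d", "Z2"),
         branch_row(5, "D8~", "D8", "D8d", "Z2"),
         branch_row(5, "D6~", "D6", "D6d", "Z2"),
         branch_row(5, "D4~", "D4", "D4d", "Z2")),
    # nc = 6
    list(branch_row(6, "O(2)~", "O(2)", "O(2)xZ2c", "1", fix = fix_unit(6, 0)),
         branch_row(6, "SO(2)1~", "SO(2)", "Z2c", "S1", fix = fix_unit(6, -1)),
         branch_row(6, "SO(2)2~", "SO(2)", "Z2xZ2c", "S1", fix = fix_unit(6, -2)),
         branch_row(6, "SO(2)3~", "SO(2)", "Z3xZ2c", "S1", fix = fix_unit(6, -3)),
         branch_row(6, "SO(2)4~", "SO(2)", "Z4xZ2c", "S1", fix = fix_unit(6, -4)),
         branch_row(6, "SO(2)5~", "SO(2)", "Z5xZ2c", "S1", fix = fix_unit(6, -5)),
         branch_row(6, "SO(2)6~", "SO(2)", "Z6xZ2c", "S1", fix = fix_unit(6, -6)),
         branch_row(6, "I~", "I", "IxZ2c", "1"),
         branch_row(6, "O~", "O", "OxZ2c", "1"),
         branch_row(6, "OT~", "O", "TxZ2c", "Z2"),
         branch_row(6, "T~", "T", "D2xZ2c", "Z3"),
         branch_row(6, "D12~", "D12", "D6xZ2c", "Z2"),
         branch_row(6, "D10~", "D10", "D5xZ2c", "Z2"),
         branch_row(6, "D8~", "D8", "D4xZ2c", "Z2"),
         branch_row(6, "D6~", "D6", "D3xZ2c", "Z2")))
}

planform_catalog <- make_catalog()

#' Synthesize a planform field
#'
#' Builds the real oscillatory pattern
#' \deqn{u(t, r) = \sum_{m=-n_c}^{n_c} c_m e^{i\omega t} Y_{n_c}^m(r) +
#'   \mathrm{c.c.}, \qquad c = z \cdot \mathrm{fix\_vector},}
#' from a catalog branch (or any user-supplied coefficient vector via the
#' `fix_vector` override).
#'
#' @param branch An `isotropy_branch` from [branches_for_degree()].
#' @param z Complex scalar amplitude.
#' @param omega Angular frequency.
#' @param t Time (scalar).
#' @param points N x 3 matrix of unit vectors (e.g. `mesh$vertices`), or a
#'   `sphere_mesh`.
#' @param fix_vector Optional complex vector of length `2*nc + 1`
#'   (overrides the catalog entry; required for branches whose fix vector
#'   is not tabulated).
#' @return Object of class `planform_field`: `values` (real field at
#'   `points`), `coefficients`, `nc`, `omega`, `t` and an evaluator
#'   `field_fun(t, points)`.
#' @export
synthesize_planform <- function(branch, z = 1, omega = 1, t = 0, points,
                                fix_vector = NULL) {
  stopifnot(inherits(branch, "isotropy_branch"))
  fv <- if (!is.null(fix_vector)) fix_vector else branch$fix_vector
  if (is.null(fv)) {
    stop("branch ", branch$name, " has no tabulated fix vector; supply one")
  }
  nc <- branch$nc
  if (length(fv) != 2 * nc + 1) stop("fix vector must have length 2*nc + 1")
  if (inherits(points, "sphere_mesh")) points <- points$vertices
  cm <- as.complex(z) * fv
  field_fun <- function(t, pts) {
    Y <- spherical_harmonic_table(pts, nc)
    cols <- nm_index(nc, -nc:nc)
    2 * Re(as.vector(Y[, cols, drop = FALSE] %*% cm) * exp(1i * omega * t))
  }
  structure(list(nc = nc, coefficients = cm, omega = omega, t = t,
                 values = field_fun(t, points), points = points,
                 field_fun = field_fun, branch = branch$name),
            class = "planform_field")
}

#' Verify a spatiotemporal symmetry of an oscillating field
#'
#' A pair \eqn{(\gamma, \psi)} of a spatial transformation and a temporal
#' phase shift is a spatiotemporal symmetry of a periodic field when
#' \eqn{u(t, \gamma^{-1} r) = u(t + \psi, r)} for all \eqn{t, r}. The
#' residual returned is the sup-norm of the difference over a sample of
#' times and points; the symmetry holds iff it is below `1e-8` (relative
#' to the field amplitude when `relative = TRUE`).
#'
#' @param field_fun Evaluator `function(t, points)` (e.g. the `field_fun`
#'   of [synthesize_planform()]).
#' @param gamma 3x3 orthogonal matrix (rotation, or inversion via
#'   [inversion()]).
#' @param phase_shift Temporal shift \eqn{\psi} (same units as `t`).
#' @param period Oscillation period (used to sample test times).
#' @param points Optional N x 3 sample points (default: a fixed
#'   deterministic set of 64 quasi-random unit vectors).
#' @param n_times Number of sample times across one period.
#' @param relative Normalize by the sup-norm of the field.
#' @return The residual (numeric scalar).
#' @export
check_spatiotemporal_symmetry <- function(field_fun, gamma, phase_shift,
                                          period, points = NULL,
                                          n_times = 7L, relative = TRUE) {
  if (is.null(points)) points <- default_sample_points()
  ginv <- t(gamma)            # orthogonal
  pts_rot <- points %*% t(ginv)
  ts <- seq(0, period, length.out = n_times + 1L)[seq_len(n_times)]
  res <- 0
  amp <- 0
  for (t in ts) {
    a <- field_fun(t, pts_rot)
    b <- field_fun(t + phase_shift, points)
    res <- max(res, max(abs(a - b)))
    amp <- max(amp, max(abs(b)))
  }
  if (relative && amp > 0) res / amp else res
}

# deterministic low-discrepancy-ish point sample on the sphere
default_sample_points <- function(n = 64L) {
  k <- seq_len(n)
  z <- (2 * k - 1) / n - 1
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Verify the catalog symmetries of a degree-4 branch
#'
#' Runs [check_spatiotemporal_symmetry()] for every stored generator of the
#' branch: elements of the spatial kernel \eqn{K} with zero phase shift,
#' twisted elements with the phase shift prescribed by \eqn{\theta}
#' (stored as a fraction of the period).
#'
#' @param branch An `isotropy_branch` with generators (the `nc = 4`
#'   catalog rows).
#' @param omega Test frequency.
#' @param z Amplitude.
#' @return Numeric vector of residuals, one per generator.
#' @export
verify_branch_symmetries <- function(branch, omega = 1, z = 0.8 + 0.3i) {
  if (is.null(branch$generators)) {
    stop("branch ", branch$name, " has no stored generator set")
  }
  pts <- default_sample_points()
  pf <- synthesize_planform(branch, z = z, omega = omega, t = 0, points = pts)
  period <- 2 * pi / omega
  vapply(branch$generators, function(g) {
    check_spatiotemporal_symmetry(pf$field_fun, g$gamma, g$phase * period,
                                  period, points = pts)
  }, numeric(1))
}
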