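#' Legendre polynomial
#'
#' Evaluates \eqn{P_n(s)} with the standard normalization \eqn{P_n(1) = 1},
#' by the three-term recurrence (stable on \eqn{[-1,1]}).
#'
#' @param n Nonnegative integer degree.
#' @param s Evaluation points in \eqn{[-1, 1]} (vectorized).
#' @return Numeric vector `P_n(s)`.
#' @export
legendre_polynomial <- function(n, s) {
  if (length(n) != 1L || n < 0 || n != round(n)) {
    stop("'n' must be a single nonnegative integer")
  }
  if (n == 0) return(rep(1, length(s)))
  pm1 <- rep(1, length(s))
  p <- s
  if (n >= 2) {
    for (k in 2:n) {
      pn <- ((2 * k - 1) * s * p - (k - 1) * pm1) / k
      pm1 <- p
      p <- pn
    }
  }
  p
}

# linear index of harmonic (n, m) in a stacked coefficient vector,
# degrees 0..n_max, orders -n..n within each degree
nm_index <- function(n, m) n * n + n + m + 1L

#' Complex orthonormal spherical harmonic
#'
#' Evaluates \eqn{Y_n^m(\theta, \phi)} in the complex orthonormal convention
#' with Condon-Shortley phase:
#' \deqn{Y_n^m = \sqrt{\frac{2n+1}{4\pi}\frac{(n-m)!}{(n+m)!}}
#'   P_n^m(\cos\theta) e^{i m \phi}, \quad m \ge 0,}
#' and \eqn{Y_n^{-m} = (-1)^m \overline{Y_n^m}}. In particular
#' \eqn{Y_0^0 = 1/\sqrt{4\pi}} and
#' \eqn{\int_\Omega Y_n^m \overline{Y_{n'}^{m'}} = \delta_{nn'}\delta_{mm'}}.
#'
#' @param n Degree, nonnegative integer.
#' @param m Order, integer with `abs(m) <= n`.
#' @param theta Colatitude in \eqn{[0, \pi]} (vectorized).
#' @param phi Azimuth in \eqn{[0, 2\pi)} (vectorized, recycled).
#' @return Complex vector.
#' @export
spherical_harmonic <- function(n, m, theta, phi) {
  if (abs(m) > n) stop("|m| must not exceed n")
  am <- abs(m)
  x <- clamp_cosine(cos(theta))
  # associated Legendre P_n^|m| with Condon-Shortley phase
  if (n == 0) {
    pnm <- rep(1, length(x))
  } else {
    pnm <- pracma::legendre(n, x)[am + 1L, ]
  }
  norm <- sqrt((2 * n + 1) / (4 * pi) * exp(lgamma(n - am + 1) - lgamma(n + am + 1)))
  y <- norm * pnm * exp(1i * am * phi)
  if (m < 0) y <- (-1)^am * Conj(y)
  y
}

# Matrix of Y_n^m values at unit-vector points, columns indexed by nm_index.
# points: N x 3 matrix of unit vectors.
spherical_harmonic_table <- function(points, n_max) {
  points <- as.matrix(points)
  z <- clamp_cosine(points[, 3])
  theta <- acos(z)
  phi <- atan2(points[, 2], points[, 1])
  N <- nrow(points)
  Y <- matrix(0i, N, (n_max + 1L)^2)
  for (n in 0:n_max) {
    pall <- if (n == 0) matrix(1, 1, N) else pracma::legendre(n, z)
    for (m in 0:n) {
      norm <- sqrt((2 * n + 1) / (4 * pi) *
                     exp(lgamma(n - m + 1) - lgamma(n + m + 1)))
      y <- norm * pall[m + 1L, ] * exp(1i * m * phi)
      Y[, nm_index(n, m)] <- y
      if (m > 0) Y[, nm_index(n, -m)] <- (-1)^m * Conj(y)
    }
  }
  Y
}

# Gauss-Legendre rule on [0, pi] (memoized)
.fh_cache <- new.env(parent = emptyenv())
gauss_theta_rule <- function(order) {
  key <- as.character(order)
  r <- .fh_cache[[key]]
  if (is.null(r)) {
    r <- pracma::gaussLegendre(order, 0, pi)
    .fh_cache[[key]] <- r
  }
  r
}

#' Funk-Hecke coefficient of a zonal kernel
#'
#' For a rotation-invariant kernel \eqn{g(r \cdot r')}, the Funk-Hecke theorem
#' states that the associated integral operator acts diagonally on spherical
#' harmonics with degree-dependent eigenvalue
#' \deqn{G_n = 2\pi \int_{-1}^{1} g(s) P_n(s) \, ds.}
#' The integral is evaluated after substituting \eqn{s = \cos\theta}
#' (the kernels of interest are smooth in the angle \eqn{\theta}, not in
#' \eqn{s}) by Gauss-Legendre quadrature with automatic order doubling until
#' two consecutive orders agree to `tol` (relative, with an absolute floor).
#'
#' @param g Function of the cosine separation, evaluable (possibly
#'   complex-valued) on \eqn{[-1, 1]}.
#' @param n Nonnegative integer degree.
#' @param quad_order Starting quadrature order (at least 2).
#' @param tol Convergence tolerance for order doubling.
#' @param max_order Order cap; exceeding it raises an error.
#' @return The (possibly complex) coefficient \eqn{G_n}.
#' @export
#' @examples
#' funk_hecke(function(s) rep(1, length(s)), 0) # 4*pi
funk_hecke <- function(g, n, quad_order = 32L, tol = 1e-10,
                       max_order = 2^14) {
  if (length(n) != 1L || n < 0 || n != round(n)) {
    stop("'n' must be a single nonnegative integer")
  }
  if (quad_order < 2) stop("quad_order must be >= 2")
  eval_at <- function(order) {
    r <- gauss_theta_rule(order)
    s <- cos(r$x)
    2 * pi * sum(r$w * g(s) * legendre_polynomial(n, s) * sin(r$x))
  }
  order <- max(quad_order, 2L)
  prev <- eval_at(order)
  repeat {
    order <- order * 2L
    if (order > max_order) {
      stop("funk_hecke did not converge below tol ", tol,
           " within order cap ", max_order)
    }
    cur <- eval_at(order)
    if (abs(cur - prev) <= tol * max(1, abs(cur))) {
      return(cur)
    }
    prev <- cur
  }
}

#' Funk-Hecke coefficient of the delayed exponential kernel
#'
#' The building block \eqn{h_n(\lambda; \sigma)} of the characteristic
#' equation: the Funk-Hecke transform of
#' \eqn{s \mapsto e^{-\arccos(s)/\sigma} e^{-\lambda \tau(s)}} with
#' \eqn{\tau(s) = \tau_0 + \arccos(s)/c}. The lumped kernel coefficient is
#' \eqn{G_n(\lambda) = J_1 h_n(\lambda;\sigma_1) + J_2 h_n(\lambda;\sigma_2)}.
#'
#' @param n Degree.
#' @param lam Complex spectral parameter (vectorized).
#' @param sigma Kernel decay scale.
#' @param delay A [delay_params()] object.
#' @param derivative If `TRUE`, return \eqn{\partial_\lambda h_n}, i.e. the
#'   transform of \eqn{-\tau(s)} times the kernel.
#' @param quad_order Starting quadrature order.
#' @param tol Convergence tolerance.
#' @return Complex vector, same length as `lam`.
#' @export
hn_coefficient <- function(n, lam, sigma, delay, derivative = FALSE,
                           quad_order = 64L, tol = 1e-10) {
  stopifnot(inherits(delay, "delay_params"))
  vapply(lam, function(l) {
    funk_hecke(function(s) {
      th <- acos(clamp_cosine(s))
      tau <- delay$tau0 + th / delay$c
      fac <- if (derivative) -tau else 1
      fac * exp(-th / sigma) * exp(-l * tau)
    }, n, quad_order = quad_order, tol = tol)
  }, complex(1))
}

#' Project a mesh field onto spherical-harmonic degrees
#'
#' Discrete projection \eqn{v_{nm} \approx \sum_i w_i u(r_i)
#' \overline{Y_n^m(r_i)}} using the mesh quadrature weights, together with the
#' power per degree \eqn{\sum_{|m| \le n} |v_{nm}|^2}.
#'
#' @param field Real (or complex) vector over mesh vertices.
#' @param mesh A [build_icosphere()] mesh.
#' @param n_max Maximum degree.
#' @return An object of class `degree_spectrum` with elements `n_max`,
#'   `coefficients` (complex, stacked by degree then order) and `power`
#'   (length `n_max + 1`).
#' @export
project_degrees <- function(field, mesh, n_max) {
  stopifnot(inherits(mesh, "sphere_mesh"))
  if (length(field) != nrow(mesh$vertices)) {
    stop("field length must equal the mesh vertex count")
  }
  if (n_max < 0) stop("n_max must be nonnegative")
  Y <- mesh_harmonics(mesh, n_max)
  v <- as.vector(crossprod(Conj(Y), mesh$weights * field))
  degree_spectrum(v, n_max)
}

degree_spectrum <- function(coefficients, n_max) {
  power <- vapply(0:n_max, function(n) {
    idx <- nm_index(n, -n:n)
    sum(Mod(coefficients[idx])^2)
  }, numeric(1))
  structure(list(n_max = n_max, coefficients = coefficients, power = power),
            class = "degree_spectrum")
}

#' @export
as.data.frame.degree_spectrum <- function(x, ...) {
  ns <- unlist(lapply(0:x$n_max, function(n) rep(n, 2 * n + 1)))
  ms <- unlist(lapply(0:x$n_max, function(n) -n:n))
  data.frame(n = ns, m = ms,
             re = Re(x$coefficients), im = Im(x$coefficients),
             degree_power = x$power[ns + 1L])
}

#' @export
print.degree_spectrum <- function(x, ...) {
  cat("degree spectrum, n_max =", x$n_max, "\n")
  cat("power by degree:\n")
  print(stats::setNames(x$power, paste0("n=", 0:x$n_max)))
  invisible(x)
}

# cached per-mesh harmonic table
mesh_harmonics <- function(mesh, n_max) {
  cache <- attr(mesh, "harmonics_cache")
  if (!is.null(cache) && !is.null(cache$Y) && cache$n_max >= n_max) {
    return(cache$Y[, seq_len((n_max + 1L)^2), drop = FALSE])
  }
  Y <- spherical_harmonic_table(mesh$vertices, n_max)
  env <- attr(mesh, "harmonics_cache")
  if (is.environment(env)) {
    env$Y <- Y
    env$n_max <- n_max
  }
  Y
}
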