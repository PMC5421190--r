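#' Coefficients of the degree-0/degree-1 double-Hopf normal form
#'
#' Container for the truncated (cubic) equivariant normal form of the
#' interaction between the degree-0 mode amplitude \eqn{w} and the
#' degree-1 mode amplitudes \eqn{z = (z_{-1}, z_0, z_1)}:
#' \deqn{\dot w = (\rho_0 + i\omega_0) w + a_1 w |w|^2 + a_2 w |z|^2,}
#' \deqn{\dot z_m = (\rho_1 + i\omega_1) z_m + b_1 z_m |z|^2 +
#'   b_2 \hat z_m (z_0^2 - 2 z_{-1} z_1) + b_3 z_m |w|^2,}
#' with \eqn{\hat z = (-\bar z_1, \bar z_0, -\bar z_{-1})}. The truncation
#' neglects quartic and higher terms, so the analysis is valid only in the
#' "simple" case \eqn{\mathrm{Re}\,a_1 \cdot \mathrm{Re}\,b_1 > 0}; the
#' `simple_case` flag records this.
#'
#' The cubic coefficients are inputs here (sampled or user-supplied): every
#' qualitative statement about the reduced dynamics is decided by their real
#' parts and the unfolding parameters alone.
#'
#' @param rho0,rho1 Real unfolding parameters (real parts of the critical
#'   eigenvalue pairs near the bifurcation; zero at it).
#' @param omega0,omega1 Positive critical frequencies.
#' @param a1,a2,b1,b2,b3 Complex cubic coefficients.
#' @return Object of class `dhopf_coefficients`.
#' @export
dhopf_coefficients <- function(rho0, rho1, omega0, omega1, a1, a2, b1, b2, b3) {
  stopifnot(omega0 > 0, omega1 > 0)
  structure(list(rho0 = rho0, rho1 = rho1, omega0 = omega0, omega1 = omega1,
                 a1 = as.complex(a1), a2 = as.complex(a2),
                 b1 = as.complex(b1), b2 = as.complex(b2), b3 = as.complex(b3),
                 simple_case = Re(a1) * Re(b1) > 0),
            class = "dhopf_coefficients")
}

#' Amplitude state of the double-Hopf normal form
#'
#' @param w Complex degree-0 amplitude.
#' @param z Complex vector `c(z_minus1, z_0, z_1)` of degree-1 amplitudes.
#' @return Object of class `amplitude_state`.
#' @export
amplitude_state <- function(w, z) {
  stopifnot(length(w) == 1L, length(z) == 3L)
  structure(list(w = as.complex(w), z = as.complex(z)),
            class = "amplitude_state")
}

# raising/lowering companion vector and the SO(3)-invariant quadratic
zhat_of <- function(z) c(-Conj(z[3]), Conj(z[2]), -Conj(z[1]))
zquad_of <- function(z) z[2]^2 - 2 * z[1] * z[3]

#' Right-hand side of the double-Hopf normal form
#'
#' @param s An [amplitude_state()].
#' @param coef A [dhopf_coefficients()] object.
#' @return An [amplitude_state()] holding the time derivative.
#' @export
normal_form_rhs <- function(s, coef) {
  stopifnot(inherits(s, "amplitude_state"), inherits(coef, "dhopf_coefficients"))
  z2 <- sum(Mod(s$z)^2)
  w2 <- Mod(s$w)^2
  dw <- (coef$rho0 + 1i * coef$omega0) * s$w + coef$a1 * s$w * w2 +
    coef$a2 * s$w * z2
  dz <- (coef$rho1 + 1i * coef$omega1) * s$z + coef$b1 * s$z * z2 +
    coef$b2 * zhat_of(s$z) * zquad_of(s$z) + coef$b3 * s$z * w2
  amplitude_state(dw, dz)
}

#' Reduction to decoupled amplitude coordinates
#'
#' The transformation
#' \eqn{(x_1, x_2, x_3) = (|w|^2,\ |z_0^2 - 2 z_{-1} z_1|,\ |z|^2)}
#' decouples the cubic normal form into a three-dimensional real ODE
#' system ([reduced_rhs()]). All three coordinates are nonnegative, and on
#' the image of the map \eqn{x_2 \le x_3}.
#'
#' @param s An [amplitude_state()].
#' @return Numeric vector `c(x1, x2, x3)`.
#' @export
reduce_state <- function(s) {
  stopifnot(inherits(s, "amplitude_state"))
  c(x1 = Mod(s$w)^2, x2 = Mod(zquad_of(s$z)), x3 = sum(Mod(s$z)^2))
}

#' Right-hand side of the reduced amplitude system
#'
#' With \eqn{\tilde a_i, \tilde b_i} the real parts of the cubic
#' coefficients,
#' \deqn{\dot x_1 = 2 x_1 (\rho_0 + \tilde a_1 x_1 + \tilde a_2 x_3),}
#' \deqn{\dot x_2 = 2 x_2 (\rho_1 + (\tilde b_1 + \tilde b_2) x_3 +
#'   \tilde b_3 x_1),}
#' \deqn{\dot x_3 = 2 x_3 (\rho_1 + \tilde b_1 x_3 + \tilde b_3 x_1) +
#'   2 \tilde b_2 x_2^2.}
#'
#' @param x Numeric vector `c(x1, x2, x3)` in the closed first octant.
#' @param coef A [dhopf_coefficients()] object.
#' @return Numeric length-3 derivative.
#' @export
reduced_rhs <- function(x, coef) {
  a1 <- Re(coef$a1); a2 <- Re(coef$a2)
  b1 <- Re(coef$b1); b2 <- Re(coef$b2); b3 <- Re(coef$b3)
  c(2 * x[1] * (coef$rho0 + a1 * x[1] + a2 * x[3]),
    2 * x[2] * (coef$rho1 + (b1 + b2) * x[3] + b3 * x[1]),
    2 * x[3] * (coef$rho1 + b1 * x[3] + b3 * x[1]) + 2 * b2 * x[2]^2)
}

reduced_jacobian <- function(x, coef) {
  a1 <- Re(coef$a1); a2 <- Re(coef$a2)
  b1 <- Re(coef$b1); b2 <- Re(coef$b2); b3 <- Re(coef$b3)
  r0 <- coef$rho0; r1 <- coef$rho1
  matrix(c(2 * (r0 + 2 * a1 * x[1] + a2 * x[3]), 0, 2 * a2 * x[1],
           2 * b3 * x[2], 2 * (r1 + (b1 + b2) * x[3] + b3 * x[1]), 2 * (b1 + b2) * x[2],
           2 * b3 * x[3], 4 * b2 * x[2], 2 * (r1 + 2 * b1 * x[3] + b3 * x[1])),
         3, 3, byrow = TRUE)
}

#' Equilibria of the reduced amplitude system in the first octant
#'
#' Enumerates the (generically at most six) equilibria of [reduced_rhs()]
#' with \eqn{x_1, x_2, x_3 \ge 0} in closed form:
#' \describe{
#'   \item{i}{the origin;}
#'   \item{ii}{the pure degree-0 point \eqn{(-\rho_0/\tilde a_1, 0, 0)}
#'     (bulk oscillation);}
#'   \item{iii}{the pure degree-1 point \eqn{(0, 0, -\rho_1/\tilde b_1)}
#'     (travelling wave);}
#'   \item{iv}{the mixed point with \eqn{x_2 = 0} solving the linear system
#'     \eqn{\rho_0 + \tilde a_1 x_1 + \tilde a_2 x_3 = 0},
#'     \eqn{\rho_1 + \tilde b_1 x_3 + \tilde b_3 x_1 = 0};}
#'   \item{v}{the \eqn{x_2 = x_3} point with \eqn{x_1 = 0},
#'     \eqn{x_3 = -\rho_1/(\tilde b_1 + \tilde b_2)};}
#'   \item{vi}{the interior \eqn{x_2 = x_3} point solving
#'     \eqn{\rho_0 + \tilde a_1 x_1 + \tilde a_2 x_3 = 0},
#'     \eqn{\rho_1 + \tilde b_3 x_1 + (\tilde b_1 + \tilde b_2) x_3 = 0}.}
#' }
#' (Any \eqn{x_2 > 0} equilibrium must satisfy \eqn{x_2 = x_3}: subtracting
#' the \eqn{x_2} balance from the \eqn{x_3} equation leaves
#' \eqn{2\tilde b_2 (x_2^2 - x_3^2) = 0}.) Points outside the closed octant
#' are discarded; each kept point carries its Jacobian eigenvalues, a
#' stability verdict and an isotropy classification.
#'
#' @param coef A [dhopf_coefficients()] object.
#' @param tol Residual/degeneracy tolerance.
#' @return A list of `octant_equilibrium` objects (fields `x`, `label`,
#'   `eigenvalues`, `stability`, `isotropy`).
#' @export
octant_equilibria <- function(coef, tol = 1e-10) {
  a1 <- Re(coef$a1); a2 <- Re(coef$a2)
  b1 <- Re(coef$b1); b2 <- Re(coef$b2); b3 <- Re(coef$b3)
  r0 <- coef$rho0; r1 <- coef$rho1
  pts <- list(i = c(0, 0, 0))
  if (abs(a1) > tol) pts$ii <- c(-r0 / a1, 0, 0)
  if (abs(b1) > tol) pts$iii <- c(0, 0, -r1 / b1)
  d_iv <- a1 * b1 - a2 * b3
  if (abs(d_iv) > tol) {
    s <- solve(matrix(c(a1, a2, b3, b1), 2, 2, byrow = TRUE), c(-r0, -r1))
    pts$iv <- c(s[1], 0, s[2])
  }
  if (abs(b1 + b2) > tol) {
    x3 <- -r1 / (b1 + b2)
    pts$v <- c(0, x3, x3)
  }
  d_vi <- a1 * (b1 + b2) - a2 * b3
  if (abs(d_vi) > tol) {
    s <- solve(matrix(c(a1, a2, b3, b1 + b2), 2, 2, byrow = TRUE), c(-r0, -r1))
    pts$vi <- c(s[1], s[2], s[2])
  }
  keep <- list()
  for (lab in names(pts)) {
    x <- pts[[lab]]
    if (any(x < -1e-12)) next
    x <- pmax(x, 0)
    if (max(abs(reduced_rhs(x, coef))) > 1e-8) next
    # drop duplicates of the origin etc. when unfolding parameters vanish
    dup <- any(vapply(keep, function(k) max(abs(k$x - x)) < 1e-10, logical(1)))
    if (dup) next
    ev <- eigen(reduced_jacobian(x, coef), only.values = TRUE)$values
    keep[[lab]] <- structure(list(x = x, label = lab, eigenvalues = ev,
                                  stability = stability_verdict(ev),
                                  isotropy = isotropy_classify(x)),
                             class = "octant_equilibrium")
  }
  unname(keep[order(vapply(keep, function(k) sum(k$x), numeric(1)))])
}

stability_verdict <- function(ev, tol = 1e-8) {
  re <- Re(ev)
  if (any(abs(re) < tol)) "degenerate" else if (all(re < 0)) "stable" else "unstable"
}

#' Stability verdict of a reduced-system equilibrium
#'
#' Classifies an equilibrium of [reduced_rhs()] from the eigenvalues of its
#' Jacobian: strictly negative real parts mean asymptotic stability in the
#' reduced variables (a necessary condition for stability of the underlying
#' pattern; the neutral phase directions of the full normal form are
#' quotiented out by the reduction).
#'
#' @param eq An `octant_equilibrium` (from [octant_equilibria()]) or a
#'   numeric `c(x1, x2, x3)`.
#' @param coef A [dhopf_coefficients()] object.
#' @param tol Margin below which the verdict is `"degenerate"`.
#' @return `"stable"`, `"unstable"` or `"degenerate"`.
#' @export
classify_stability <- function(eq, coef, tol = 1e-8) {
  x <- if (inherits(eq, "octant_equilibrium")) eq$x else eq
  ev <- eigen(reduced_jacobian(x, coef), only.values = TRUE)$values
  stability_verdict(ev, tol)
}

#' Isotropy type of a reduced-state sign pattern
#'
#' Maps the sign pattern of \eqn{(x_1, x_2, x_3)} (with the \eqn{x_2 = x_3}
#' equality information) onto the catalog of isotropy types of the
#' double-Hopf normal form. The reduced coordinates do not always determine
#' the isotropy uniquely (e.g. \eqn{(0, 0, x_3)} is realized both by a pure
#' travelling wave and by generic mixed degree-1 modes with
#' \eqn{z_0^2 = 2 z_{-1} z_1}), so the most symmetric compatible row is
#' returned as `row`, with the other candidates in `compatible`.
#'
#' @param x Numeric `c(x1, x2, x3)` (or an `octant_equilibrium`).
#' @param tol Equality/positivity tolerance.
#' @return List with `row` (integer 1-8, or `NA` for the homogeneous state
#'   `x = 0`), `name`, `pattern` and `compatible`.
#' @export
isotropy_classify <- function(x, tol = 1e-9) {
  if (inherits(x, "octant_equilibrium")) x <- x$x
  pos <- x > tol
  eq23 <- abs(x[2] - x[3]) <= tol * max(1, x[3])
  row <- NA_integer_; name <- "homogeneous"; compat <- integer(0)
  if (!any(pos)) {
    # origin: no pattern
  } else if (pos[1] && !pos[2] && !pos[3]) {
    row <- 1L; name <- "bulk oscillation"
  } else if (!pos[1] && !pos[2] && pos[3]) {
    row <- 2L; name <- "travelling wave"; compat <- 5L
  } else if (!pos[1] && pos[2] && pos[3]) {
    if (eq23) {
      row <- 3L; name <- "standing wave"; compat <- c(4L, 5L)
    } else {
      row <- 5L; name <- "mixed degree-1 modes"; compat <- 4L
    }
  } else if (pos[1] && !pos[2] && pos[3]) {
    row <- 7L; name <- "mixed bulk and degree-1 (x2 = 0)"; compat <- 8L
  } else if (pos[1] && pos[2] && pos[3]) {
    if (eq23) {
      row <- 6L; name <- "mixed bulk and standing wave"; compat <- 8L
    } else {
      row <- 8L; name <- "no symmetry"
    }
  } else {
    return(list(row = NA_integer_, name = "unclassified",
                pattern = x, compatible = integer(0)))
  }
  list(row = row, name = name, pattern = x, compatible = compat)
}

#' @export
print.octant_equilibrium <- function(x, ...) {
  cat(sprintf("equilibrium %-3s x = (%.4g, %.4g, %.4g)  [%s]  %s\n",
              x$label, x$x[1], x$x[2], x$x[3], x$stability, x$isotropy$name))
  invisible(x)
}

#' Sample random double-Hopf coefficient sets
#'
#' Draws coefficient sets with \eqn{\rho_0, \rho_1 > 0} and strictly
#' negative real parts of all five cubic coefficients (log-normal
#' magnitudes), the regime in which the truncated normal form is
#' dissipative. With `regime = "all_six"` the magnitudes are additionally
#' constrained to the cross-coupling-dominated regime
#' \eqn{\tilde b_3 \tilde a_2 > \tilde a_1 (\tilde b_1 + \tilde b_2)},
#' \eqn{|\tilde b_3| \rho_0 > |\tilde a_1| \rho_1},
#' \eqn{|\tilde a_2| \rho_1 > (|\tilde b_1| + |\tilde b_2|) \rho_0},
#' in which all six octant equilibria coexist.
#'
#' @param n Number of sets.
#' @param seed RNG seed.
#' @param regime `"generic"` or `"all_six"`.
#' @return List of [dhopf_coefficients()].
#' @export
sample_dhopf_coefficients <- function(n, seed = 1L, regime = c("generic", "all_six")) {
  regime <- match.arg(regime)
  set.seed(seed)
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    rho <- stats::runif(2, 0.2, 1)
    mag <- exp(stats::rnorm(5, 0, 0.7))
    im <- stats::rnorm(5, 0, 0.5)
    co <- dhopf_coefficients(rho[1], rho[2], omega0 = 1, omega1 = exp(1) / 2,
                             a1 = -mag[1] + 1i * im[1], a2 = -mag[2] + 1i * im[2],
                             b1 = -mag[3] + 1i * im[3], b2 = -mag[4] + 1i * im[4],
                             b3 = -mag[5] + 1i * im[5])
    if (regime == "all_six") {
      A <- mag[1]; B <- mag[2]; C <- mag[3]; D <- mag[4]; E <- mag[5]
      ok <- (B * E > A * (C + D)) && (E * rho[1] > A * rho[2]) &&
        (B * rho[2] > (C + D) * rho[1])
      if (!ok) next
    }
    i <- i + 1L
    out[[i]] <- co
  }
  out
}

# --- integration helpers (oracle-grade, used by tests and vignette) -------

# integrate the full complex normal form as an 8-dim real system
integrate_normal_form <- function(s0, coef, times, rtol = 1e-10, atol = 1e-12) {
  y0 <- c(Re(s0$w), Im(s0$w), Re(s0$z), Im(s0$z))
  rhs <- function(t, y, parms) {
    s <- amplitude_state(complex(real = y[1], imaginary = y[2]),
                         complex(real = y[3:5], imaginary = y[6:8]))
    d <- normal_form_rhs(s, coef)
    list(c(Re(d$w), Im(d$w), Re(d$z), Im(d$z)))
  }
  sol <- deSolve::ode(y0, times, rhs, NULL, rtol = rtol, atol = atol)
  t(apply(sol[, -1, drop = FALSE], 1, function(y) {
    reduce_state(amplitude_state(complex(real = y[1], imaginary = y[2]),
                                 complex(real = y[3:5], imaginary = y[6:8])))
  }))
}

integrate_reduced <- function(x0, coef, times, rtol = 1e-10, atol = 1e-12) {
  rhs <- function(t, y, parms) list(reduced_rhs(y, coef))
  sol <- deSolve::ode(x0, times, rhs, NULL, rtol = rtol, atol = atol)
  sol[, -1, drop = FALSE]
}

# brute-force multistart enumeration of octant equilibria (test oracle).
# Newton preserves the coordinate planes {x_i = 0}, so starts cycle through
# all zero-masks to reach boundary equilibria; the box is scaled to the
# coefficient magnitudes.
octant_equilibria_multistart <- function(coef, n_starts = 200L, seed = 1L,
                                         box = NULL) {
  set.seed(seed)
  if (is.null(box)) {
    # coordinate bounds satisfied by every octant root when the cubic real
    # parts are negative: x1 <= rho0/|a1~|, x3 <= rho1/min(|b1~|, |b1~+b2~|)
    b1 <- 1.5 * abs(coef$rho0) / max(abs(Re(coef$a1)), 1e-3)
    b3 <- 1.5 * abs(coef$rho1) /
      max(min(abs(Re(coef$b1)), abs(Re(coef$b1) + Re(coef$b2))), 1e-3)
    box <- c(b1, b3, b3)
  } else if (length(box) == 1L) {
    box <- rep(box, 3L)
  }
  masks <- list(c(1, 1, 1), c(1, 0, 0), c(0, 0, 1), c(1, 0, 1),
                c(0, 1, 1), c(0, 0, 0))
  found <- list()
  for (k in seq_len(n_starts)) {
    # squared-uniform radii also cover roots with very small coordinates
    x <- box * stats::runif(3)^2 * masks[[(k %% length(masks)) + 1L]]
    # the x2 > 0 equilibria satisfy x2 = x3; bias half the masked starts
    if (k %% 2L == 0L && x[2] > 0) x[3] <- x[2]
    for (it in 1:400) {
      f <- reduced_rhs(x, coef)
      if (max(abs(f)) < 1e-12) break
      J <- reduced_jacobian(x, coef)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      step <- step * min(1, 2 / max(abs(step)))
      lam <- 1
      repeat {
        xn <- x + lam * step
        if (sum(abs(reduced_rhs(xn, coef))) < sum(abs(f)) || lam < 1e-6) break
        lam <- lam / 2
      }
      x <- xn
    }
    if (max(abs(reduced_rhs(x, coef))) < 1e-10 && all(x > -1e-9)) {
      x <- pmax(x, 0)
      if (!length(found) ||
          min(vapply(found, function(g) max(abs(g - x)), numeric(1))) > 1e-6) {
        found[[length(found) + 1L]] <- x
      }
    }
  }
  found
}
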