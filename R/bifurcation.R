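#' Fold/transcritical line of one harmonic degree
#'
#' Setting \eqn{\lambda = 0} in the characteristic equation yields the line
#' \deqn{\kappa J_1 h_n(0;\sigma_1) + \kappa J_2 h_n(0;\sigma_2) = 1}
#' in the lumped-gain plane, the locus of candidate fold/transcritical
#' bifurcations of degree `n`.
#'
#' @param n Degree.
#' @param sigma1,sigma2 Kernel scales.
#' @param delay A [delay_params()] object (the line itself is
#'   delay-independent since \eqn{e^{-0\cdot\tau} = 1}, but the delay is part
#'   of the model template).
#' @return List with coefficients `a`, `b` of `a*kJ1 + b*kJ2 = 1` (the
#'   degree-n kernel coefficients at zero), plus `n`.
#' @export
fold_line <- function(n, sigma1, sigma2, delay) {
  a <- Re(hn_coefficient(n, 0, sigma1, delay))
  b <- Re(hn_coefficient(n, 0, sigma2, delay))
  if (abs(a) < 1e-14 && abs(b) < 1e-14) {
    stop("degenerate fold line: both kernel coefficients vanish at degree ", n)
  }
  list(n = as.integer(n), a = a, b = b)
}

#' Parametric Hopf curve of one harmonic degree
#'
#' Setting \eqn{\lambda = i\omega} in the characteristic equation and
#' splitting into real and imaginary parts gives, for each \eqn{\omega > 0},
#' a 2x2 linear system for the lumped gains:
#' \deqn{\begin{pmatrix}\mathrm{Re}\,h_n(i\omega;\sigma_1) &
#'   \mathrm{Re}\,h_n(i\omega;\sigma_2)\\ \mathrm{Im}\,h_n(i\omega;\sigma_1) &
#'   \mathrm{Im}\,h_n(i\omega;\sigma_2)\end{pmatrix}
#'   \begin{pmatrix}\kappa J_1\\ \kappa J_2\end{pmatrix} =
#'   \begin{pmatrix}1\\ \omega\end{pmatrix}.}
#' Each solved point is certified by the residual
#' \eqn{|E_n(i\omega)| \le} `residual_tol`; \eqn{\omega} values where the
#' matrix is numerically singular (condition number beyond `cond_max`) are
#' skipped and reported in the `skipped` attribute.
#'
#' @param n Degree.
#' @param omega_grid Positive frequencies to trace.
#' @param sigma1,sigma2 Kernel scales.
#' @param delay A [delay_params()] object.
#' @param cond_max Condition-number cutoff.
#' @param residual_tol Certification tolerance.
#' @return Data frame with columns `n`, `omega`, `kJ1`, `kJ2`, `residual`.
#' @export
hopf_curve <- function(n, omega_grid, sigma1, sigma2, delay,
                       cond_max = 1e10, residual_tol = 1e-9) {
  stopifnot(all(omega_grid > 0))
  rows <- lapply(omega_grid, function(w) {
    h1 <- hn_coefficient(n, 1i * w, sigma1, delay)
    h2 <- hn_coefficient(n, 1i * w, sigma2, delay)
    M <- rbind(c(Re(h1), Re(h2)), c(Im(h1), Im(h2)))
    if (!all(is.finite(M)) || kappa_cond(M) > cond_max) return(NULL)
    kj <- solve(M, c(1, w))
    resid <- abs(1i * w + 1 - (kj[1] * h1 + kj[2] * h2))
    if (resid > residual_tol) return(NULL)
    data.frame(n = as.integer(n), omega = w, kJ1 = kj[1], kJ2 = kj[2],
               residual = resid)
  })
  skipped <- omega_grid[vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(n = integer(0), omega = numeric(0), kJ1 = numeric(0),
                      kJ2 = numeric(0), residual = numeric(0))
  }
  attr(out, "skipped") <- skipped
  out
}

kappa_cond <- function(M) {
  s <- svd(M, nu = 0, nv = 0)$d
  if (min(s) == 0) Inf else max(s) / min(s)
}

#' Hopf point on the balanced-kernel line
#'
#' Intersects the degree-`n` Hopf curve with the balanced-kernel line
#' \eqn{\kappa J_1 h_0(0;\sigma_1) + \kappa J_2 h_0(0;\sigma_2) = 0} in the
#' lumped plane. On this line the kernel mass vanishes, \eqn{\hat u = 0} is
#' the unique homogeneous equilibrium, and \eqn{\kappa = f'(0)} is explicit
#' in the firing parameters, which makes the point a convenient anchor for
#' normal-form continuation. Among the intersections the one nearest the
#' origin on the requested side (`kJ1_sign`) is returned; all intersections
#' found are attached as attribute `all_points`.
#'
#' @param n Degree of the Hopf curve (default 0).
#' @param sigma1,sigma2 Kernel scales.
#' @param delay A [delay_params()] object.
#' @param omega_range Frequency window scanned for intersections.
#' @param kJ1_sign Select the branch with this sign of \eqn{\kappa J_1}.
#' @return A `hopf_point` list: `n`, `omega`, `kJ1`, `kJ2`, `sigma1`,
#'   `sigma2`, `delay`, `residual` (certificate \eqn{|E_n(i\omega)|}).
#' @export
balanced_hopf_point <- function(n = 0L, sigma1, sigma2, delay,
                                omega_range = c(0.02, 3), kJ1_sign = 1) {
  a0 <- Re(hn_coefficient(0, 0, sigma1, delay))
  b0 <- Re(hn_coefficient(0, 0, sigma2, delay))
  bal <- function(w) {
    h1 <- hn_coefficient(n, 1i * w, sigma1, delay)
    h2 <- hn_coefficient(n, 1i * w, sigma2, delay)
    M <- rbind(c(Re(h1), Re(h2)), c(Im(h1), Im(h2)))
    kj <- solve(M, c(1, w))
    a0 * kj[1] + b0 * kj[2]
  }
  ws <- seq(omega_range[1], omega_range[2], length.out = 400L)
  vals <- vapply(ws, function(w) tryCatch(bal(w), error = function(e) NA_real_),
                 numeric(1))
  idx <- which(!is.na(vals[-1]) & !is.na(vals[-length(vals)]) &
                 vals[-1] * vals[-length(vals)] < 0)
  if (!length(idx)) stop("no balanced Hopf intersection in the frequency window")
  pts <- lapply(idx, function(i) {
    w <- stats::uniroot(bal, c(ws[i], ws[i + 1L]), tol = 1e-13)$root
    hopf_point(n, w, sigma1, sigma2, delay)
  })
  side <- vapply(pts, function(p) sign(p$kJ1) == sign(kJ1_sign), logical(1))
  cand <- pts[side]
  if (!length(cand)) stop("no balanced Hopf point with the requested kJ1 sign")
  d <- vapply(cand, function(p) p$kJ1^2 + p$kJ2^2, numeric(1))
  out <- cand[[which.min(d)]]
  attr(out, "all_points") <- pts
  out
}

#' Certified Hopf point at a given frequency
#'
#' Solves the 2x2 Hopf-curve system at a single frequency and certifies the
#' characteristic residual.
#'
#' @inheritParams balanced_hopf_point
#' @param omega Critical frequency.
#' @return A `hopf_point` list.
#' @export
hopf_point <- function(n, omega, sigma1, sigma2, delay) {
  stopifnot(omega > 0)
  h1 <- hn_coefficient(n, 1i * omega, sigma1, delay)
  h2 <- hn_coefficient(n, 1i * omega, sigma2, delay)
  M <- rbind(c(Re(h1), Re(h2)), c(Im(h1), Im(h2)))
  kj <- solve(M, c(1, omega))
  resid <- abs(1i * omega + 1 - (kj[1] * h1 + kj[2] * h2))
  if (resid > 1e-9) stop("Hopf point certificate failed: residual ", resid)
  structure(list(n = as.integer(n), omega = omega, kJ1 = kj[1], kJ2 = kj[2],
                 sigma1 = sigma1, sigma2 = sigma2, delay = delay,
                 residual = resid),
            class = "hopf_point")
}

#' @export
print.hopf_point <- function(x, ...) {
  cat(sprintf("Hopf point (degree n=%d): omega=%.6f kJ1=%.6f kJ2=%.6f (|E_n(i omega)|=%.1e)\n",
              x$n, x$omega, x$kJ1, x$kJ2, x$residual))
  invisible(x)
}

#' Linear stability mask over the lumped-gain plane
#'
#' Evaluates the sign of the rightmost eigenvalue real part on a grid of
#' lumped gains. Cells where the spectral solve fails are marked `NA`
#' ("unknown"), never silently stable.
#'
#' @param kJ1_grid,kJ2_grid Grid coordinates (should contain the origin,
#'   which is provably stable).
#' @param sigma1,sigma2 Kernel scales.
#' @param delay A [delay_params()] object.
#' @param n_max Degree truncation of the stability verdict.
#' @param seed_grid Newton seed-grid resolution per cell (coarser than the
#'   default spectral grid: only the rightmost root matters here).
#' @return Data frame with columns `kJ1`, `kJ2`, `max_re`, `stable`.
#' @export
stability_mask <- function(kJ1_grid, kJ2_grid, sigma1, sigma2, delay,
                           n_max = 10L, seed_grid = 10L) {
  grid <- expand.grid(kJ1 = kJ1_grid, kJ2 = kJ2_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ctx <- lumped_context(grid$kJ1[i], grid$kJ2[i], sigma1, sigma2, delay,
                          n_max = n_max)
    tryCatch({
      ev <- rightmost_eigenvalue(ctx, grid = seed_grid)
      c(Re(ev$lam), as.numeric(Re(ev$lam) < 0))
    }, error = function(e) c(NA_real_, NA_real_))
  })
  grid$max_re <- vapply(res, `[`, numeric(1), 1L)
  grid$stable <- as.logical(vapply(res, `[`, numeric(1), 2L))
  grid
}

#' Cubic normal-form coefficient of the degree-0 Hopf bifurcation
#'
#' `normal_form_g21` is the raw formula: with critical frequency
#' \eqn{\omega_0}, linearization gain \eqn{\kappa}, lumped kernel derivative
#' \eqn{\kappa G_0'(i\omega_0)} and resolvent ratios \eqn{Q_0(2i\omega_0)},
#' \eqn{Q_0(0)},
#' \deqn{g_{21} = \frac{1 + i\omega_0}{8\pi\kappa(1 - \kappa G_0'(i\omega_0))}
#'   \left(f'''(\hat u) + f''(\hat u)^2 \left[Q_0(2i\omega_0) + 2 Q_0(0)\right]
#'   \right),}
#' and the first Lyapunov coefficient is
#' \eqn{l_1 = \mathrm{Re}(g_{21})/\omega_0}: negative means supercritical,
#' positive subcritical.
#'
#' @param omega0 Critical frequency.
#' @param kappa Linearization gain \eqn{f'(\hat u)}.
#' @param kG0p Lumped kernel derivative \eqn{\kappa G_0'(i\omega_0)}.
#' @param Q0_2iw,Q0_0 Resolvent ratios \eqn{Q_0(2i\omega_0)}, \eqn{Q_0(0)}.
#' @param f2,f3 Second and third derivative of the firing rate at the
#'   equilibrium.
#' @return Complex \eqn{g_{21}}.
#' @export
normal_form_g21 <- function(omega0, kappa, kG0p, Q0_2iw, Q0_0, f2, f3) {
  (1 + 1i * omega0) / (8 * pi * kappa * (1 - kG0p)) *
    (f3 + f2^2 * (Q0_2iw + 2 * Q0_0))
}

#' First Lyapunov coefficient at a balanced degree-0 Hopf point
#'
#' Evaluates the cubic normal-form coefficient \eqn{g_{21}} and
#' \eqn{l_1 = \mathrm{Re}(g_{21})/\omega_0} for a degree-0 Hopf point on the
#' balanced-kernel line, where \eqn{\hat u = 0} and all firing-rate
#' derivatives are explicit. On the Hopf curve
#' \eqn{\kappa G_0(i\omega_0) = 1 + i\omega_0} holds by construction; the
#' lumped quantities \eqn{\kappa G_0(\mu)} at \eqn{\mu \in \{0,
#' 2i\omega_0\}} and \eqn{\kappa G_0'(i\omega_0)} are computed from the
#' point's gains, while \eqn{\kappa}, \eqn{f''}, \eqn{f'''} come from the
#' firing parameters. Non-resonance (simplicity of the critical pair and
#' regularity of \eqn{0} and \eqn{2i\omega_0}) is checked and violation is
#' an error.
#'
#' @param hp A `hopf_point` with `n == 0` (see [balanced_hopf_point()]).
#' @param firing A [firing_params()] object.
#' @return An object of class `normal_form_result`: `g21`, `l1`, `omega0`,
#'   `criticality` (`"supercritical"`/`"subcritical"`/`"degenerate"`), and
#'   `diagnostics` (`Q0_0`, `Q0_2iw`, `kG0p`, `kappa`; the derivative
#'   \eqn{G_0'} is evaluated at the critical eigenvalue \eqn{i\omega_0}).
#' @export
lyapunov_coefficient <- function(hp, firing) {
  stopifnot(inherits(hp, "hopf_point"), inherits(firing, "firing_params"))
  if (hp$n != 0L) {
    stop("the scalar cubic normal form applies to the degree-0 Hopf ",
         "bifurcation only (simple critical pair)")
  }
  u_hat <- 0  # balanced convention
  kap <- firing_rate_derivative(u_hat, firing, 1L)
  f2 <- firing_rate_derivative(u_hat, firing, 2L)
  f3 <- firing_rate_derivative(u_hat, firing, 3L)
  lumped <- function(mu, derivative = FALSE) {
    hp$kJ1 * hn_coefficient(hp$n, mu, hp$sigma1, hp$delay, derivative = derivative) +
      hp$kJ2 * hn_coefficient(hp$n, mu, hp$sigma2, hp$delay, derivative = derivative)
  }
  E0 <- function(mu) mu + 1 - lumped(mu)
  # non-resonance: 0 and 2i*omega0 must be regular values of E_0
  for (mu in c(0, 2i * hp$omega)) {
    if (abs(E0(mu)) <= 1e-8) {
      stop("resonance: E_0 is (near-)singular at mu = ", format(mu))
    }
  }
  Q0 <- function(mu) (lumped(mu) / kap) / E0(mu)
  kG0p <- lumped(1i * hp$omega, derivative = TRUE)
  g21 <- normal_form_g21(hp$omega, kap, kG0p, Q0(2i * hp$omega), Q0(0), f2, f3)
  l1 <- Re(g21) / hp$omega
  crit <- if (abs(l1) < 1e-12) "degenerate" else if (l1 < 0) "supercritical" else "subcritical"
  structure(list(g21 = g21, l1 = l1, omega0 = hp$omega, criticality = crit,
                 diagnostics = list(Q0_0 = Q0(0), Q0_2iw = Q0(2i * hp$omega),
                                    kG0p = kG0p, kappa = kap,
                                    derivative_argument = "i*omega0")),
            class = "normal_form_result")
}

#' @export
print.normal_form_result <- function(x, ...) {
  cat(sprintf("g21 = %.6g%+.6gi, l1 = %.6g (%s), omega0 = %.6f\n",
              Re(x$g21), Im(x$g21), x$l1, x$criticality, x$omega0))
  invisible(x)
}

#' Generalized-Hopf (Bautin) point along the firing-threshold continuation
#'
#' Holds the degree-0 Hopf point fixed at the balanced-kernel intersection
#' (where \eqn{\hat u = 0} and \eqn{\kappa} is explicit) and varies the
#' firing threshold \eqn{\delta}: the first Lyapunov coefficient
#' \eqn{l_1(\delta)} changes sign at a generalized Hopf bifurcation, the
#' organizing center for bistability between rest and oscillation. The zero
#' is located by bisection.
#'
#' @param alpha,beta Firing parameters held fixed along the continuation.
#' @param delta_interval Interval scanned for the sign change of \eqn{l_1}.
#' @param sigma1,sigma2 Kernel scales.
#' @param delay A [delay_params()] object.
#' @param l1_tol Bisection continues until \eqn{|l_1|} at the midpoint drops
#'   below this (or the interval reaches machine precision).
#' @return An object of class `codim2_point` with `kind =
#'   "generalized_hopf"`, `delta_star`, the underlying `hopf_point`,
#'   `omega0`, firing parameters at the point and certificate residuals.
#' @export
find_generalized_hopf <- function(alpha, beta, delta_interval, sigma1, sigma2,
                                  delay, l1_tol = 1e-8) {
  hp <- balanced_hopf_point(0L, sigma1, sigma2, delay)
  l1_of <- function(delta) {
    lyapunov_coefficient(hp, firing_params(alpha, beta, delta))$l1
  }
  lo <- delta_interval[1]
  hi <- delta_interval[2]
  flo <- l1_of(lo)
  fhi <- l1_of(hi)
  if (sign(flo) == sign(fhi)) {
    stop("l1 does not change sign on the given delta interval (l1 = ",
         signif(flo, 4), " and ", signif(fhi, 4), ")")
  }
  mid <- (lo + hi) / 2
  fmid <- l1_of(mid)
  while (abs(fmid) > l1_tol && (hi - lo) > .Machine$double.eps * max(1, abs(hi))) {
    if (sign(fmid) == sign(flo)) {
      lo <- mid
      flo <- fmid
    } else {
      hi <- mid
    }
    mid <- (lo + hi) / 2
    fmid <- l1_of(mid)
  }
  structure(list(kind = "generalized_hopf", delta_star = mid,
                 omega0 = hp$omega, hopf_point = hp,
                 firing = firing_params(alpha, beta, mid),
                 certificates = c(E0_residual = hp$residual, l1 = abs(fmid))),
            class = "codim2_point")
}

#' Double-Hopf point of the degree-0 and degree-1 modes
#'
#' Locates parameters at which the characteristic equations of degrees 0 and
#' 1 each have a purely imaginary root pair simultaneously. The search runs
#' along the balanced-kernel family (so \eqn{\hat u = 0} solves the
#' equilibrium equation identically and \eqn{\kappa = f'(0)} is explicit)
#' with the offset delay \eqn{\tau_0} as the unfolding parameter: the five
#' unknowns \eqn{(J_1, J_2, \tau_0, \omega_0, \omega_1)} solve
#' \deqn{w_0(J_1,J_2) = 0,\quad E_0(i\omega_0) = 0,\quad E_1(i\omega_1) = 0}
#' (the last two complex), by damped Newton with a finite-difference
#' Jacobian. Non-resonance \eqn{k\omega_0 \ne l\omega_1} for
#' \eqn{k + l \le 5} is verified at the solution.
#'
#' @param firing A [firing_params()] object (held fixed).
#' @param sigma1,sigma2 Kernel scales.
#' @param c Propagation speed.
#' @param tau0_init Starting offset delay.
#' @param start Optional numeric starting vector
#'   `c(J1, J2, tau0, omega0, omega1)`; if `NULL` it is seeded from the
#'   balanced degree-0 Hopf point at `tau0_init` and the rightmost degree-1
#'   eigenvalue there.
#' @param tol Residual tolerance of the 5-equation system.
#' @param max_iter Newton iteration cap.
#' @return An object of class `codim2_point` with `kind = "double_hopf"`:
#'   full [model_params()], `omega0`, `omega1`, certificate residuals and
#'   the non-resonance margin.
#' @export
find_double_hopf <- function(firing, sigma1, sigma2, c, tau0_init = 3,
                             start = NULL, tol = 1e-10, max_iter = 80L) {
  stopifnot(inherits(firing, "firing_params"))
  kap <- firing_rate_derivative(0, firing, 1L)
  resfun <- function(x) {
    J1 <- x[1]; J2 <- x[2]; t0 <- x[3]; w0 <- x[4]; w1 <- x[5]
    if (t0 < 0 || w0 <= 0 || w1 <= 0) return(rep(1e6, 5))
    dl <- delay_params(t0, c)
    E0 <- 1i * w0 + 1 - kap * (J1 * hn_coefficient(0, 1i * w0, sigma1, dl) +
                                 J2 * hn_coefficient(0, 1i * w0, sigma2, dl))
    E1 <- 1i * w1 + 1 - kap * (J1 * hn_coefficient(1, 1i * w1, sigma1, dl) +
                                 J2 * hn_coefficient(1, 1i * w1, sigma2, dl))
    bal <- J1 * Re(hn_coefficient(0, 0, sigma1, dl)) +
      J2 * Re(hn_coefficient(0, 0, sigma2, dl))
    c(bal, Re(E0), Im(E0), Re(E1), Im(E1))
  }
  if (is.null(start)) {
    dl0 <- delay_params(tau0_init, c)
    hp <- balanced_hopf_point(0L, sigma1, sigma2, dl0)
    conn0 <- connectivity_params(hp$kJ1 / kap, hp$kJ2 / kap, sigma1, sigma2)
    ctx0 <- lumped_context(hp$kJ1, hp$kJ2, sigma1, sigma2, dl0, n_max = 1L)
    ev1 <- solve_modes(ctx0, 1L)
    w1_seed <- if (nrow(ev1) && abs(Im(ev1$lam[1])) > 1e-6) abs(Im(ev1$lam[1])) else 0.6 * hp$omega
    start <- c(conn0$J1, conn0$J2, tau0_init, hp$omega, w1_seed)
  }
  x <- start
  f0 <- resfun(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(f0)) < tol) break
    J <- matrix(0, 5, 5)
    for (j in 1:5) {
      dx <- 1e-7 * max(1, abs(x[j]))
      xp <- x
      xp[j] <- x[j] + dx
      J[, j] <- (resfun(xp) - f0) / dx
    }
    step <- tryCatch(solve(J, -f0), error = function(e) NULL)
    if (is.null(step)) stop("double-Hopf Newton: singular Jacobian")
    lam <- 1
    repeat {
      xn <- x + lam * step
      fn <- resfun(xn)
      if (sum(abs(fn)) < sum(abs(f0)) || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- xn
    f0 <- fn
  }
  if (max(abs(f0)) >= tol) {
    stop("double-Hopf solve did not converge: residual ", max(abs(f0)))
  }
  w0 <- x[4]; w1 <- x[5]
  # non-resonance k*w0 != l*w1 for k+l <= 5
  margin <- Inf
  for (k in 1:4) for (l in 1:(5 - k)) {
    margin <- min(margin, abs(k * w0 - l * w1))
  }
  if (margin < 1e-3) {
    stop("resonant double Hopf: |k*omega0 - l*omega1| = ", margin)
  }
  params <- model_params(firing,
                         connectivity_params(x[1], x[2], sigma1, sigma2),
                         delay_params(x[3], c))
  structure(list(kind = "double_hopf", params = params,
                 omega0 = w0, omega1 = w1, tau0 = x[3],
                 J1 = x[1], J2 = x[2],
                 certificates = stats::setNames(abs(f0),
                   c("balance", "ReE0", "ImE0", "ReE1", "ImE1")),
                 nonresonance_margin = margin),
            class = "codim2_point")
}

#' @export
print.codim2_point <- function(x, ...) {
  cat("codimension-2 point:", x$kind, "\n")
  if (x$kind == "generalized_hopf") {
    cat(sprintf("  delta* = %.6f, omega0 = %.6f, (kJ1, kJ2) = (%.4f, %.4f)\n",
                x$delta_star, x$omega0, x$hopf_point$kJ1, x$hopf_point$kJ2))
  } else {
    cat(sprintf("  J1 = %.4f, J2 = %.4f, tau0 = %.4f, omega0 = %.4f, omega1 = %.4f\n",
                x$J1, x$J2, x$tau0, x$omega0, x$omega1))
  }
  cat("  certificates:", paste(sprintf("%.2e", x$certificates), collapse = " "), "\n")
  invisible(x)
}
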