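#' Linearization context for the spectral problem
#'
#' Bundles parameters, a homogeneous equilibrium and the degree truncation
#' used by the characteristic equations
#' \eqn{E_n(\lambda) = \lambda + 1 - \kappa G_n(\lambda)}, where
#' \eqn{G_n(\lambda)} is the Funk-Hecke coefficient of
#' \eqn{w(s) e^{-\lambda \tau(s)}} and \eqn{\kappa = f'(\hat u)}.
#'
#' The context precomputes a converged Gauss-Legendre rule (order chosen by
#' doubling until \eqn{G_n} is stable to 1e-11 at the most oscillatory point
#' of the default search box) so that repeated evaluations during root
#' finding reduce to dot products.
#'
#' @param params A [model_params()] object.
#' @param equilibrium An `equilibrium` object (from [find_equilibria()] or
#'   [calibrate_couplings()]). If `NULL`, equilibria are computed and, when
#'   several exist, the branch whose leading degree-0 eigenvalue pair is
#'   closest to the imaginary axis is selected (the destabilizing branch;
#'   the choice is recorded in the `branch_note` field).
#' @param n_max Degree truncation for whole-spectrum queries (default 10).
#' @param quad_order Optional fixed quadrature order (otherwise adaptive).
#' @return An object of class `linearization_context`.
#' @export
linearization_context <- function(params, equilibrium = NULL, n_max = 10L,
                                  quad_order = NULL) {
  stopifnot(inherits(params, "model_params"))
  branch_note <- NULL
  if (is.null(equilibrium)) {
    eqs <- find_equilibria(params)
    if (length(eqs) > 1L) {
      # provisional contexts (fixed modest order) rank the branches
      dist <- vapply(eqs, function(eq) {
        ctx <- new_linctx(params, eq, 0L, 256L, NULL)
        ev <- tryCatch(rightmost_eigenvalue(ctx), error = function(e) NULL)
        if (is.null(ev)) Inf else abs(Re(ev$lam))
      }, numeric(1))
      sel <- which.min(dist)
      branch_note <- sprintf(
        "selected equilibrium branch %d of %d (u_hat=%.6g): leading degree-0 eigenvalue closest to the imaginary axis",
        sel, length(eqs), eqs[[sel]]$u_hat)
      equilibrium <- eqs[[sel]]
    } else {
      equilibrium <- eqs[[1L]]
    }
  }
  stopifnot(inherits(equilibrium, "equilibrium"))
  if (equilibrium$residual > 1e-8) {
    stop("equilibrium residual ", equilibrium$residual,
         " exceeds 1e-8; not consistent with the parameters")
  }
  new_linctx(params, equilibrium, n_max, quad_order, branch_note)
}

new_linctx <- function(params, equilibrium, n_max, quad_order, branch_note) {
  ctx <- structure(list(params = params, equilibrium = equilibrium,
                        n_max = as.integer(n_max),
                        kappa = equilibrium$kappa,
                        delay = params$delay,
                        connectivity = params$connectivity,
                        branch_note = branch_note,
                        cache = new.env(parent = emptyenv())),
                   class = "linearization_context")
  ctx$quad_order <- if (is.null(quad_order)) choose_quad_order(ctx) else as.integer(quad_order)
  ctx
}

#' Linearization context from lumped coupling gains
#'
#' The characteristic equations depend on the couplings only through the
#' lumped gains \eqn{(\kappa J_1, \kappa J_2)}. This constructor builds a
#' context directly from those gains (internally \eqn{\kappa = 1},
#' \eqn{J_i = \kappa J_i}), convenient for analyses parametrized in the
#' lumped plane where no specific firing rate is implied.
#'
#' @param kJ1,kJ2 Lumped gains.
#' @param sigma1,sigma2 Kernel scales.
#' @param delay A [delay_params()] object.
#' @param n_max Degree truncation.
#' @param quad_order Optional fixed quadrature order.
#' @return A `linearization_context`.
#' @export
lumped_context <- function(kJ1, kJ2, sigma1, sigma2, delay, n_max = 10L,
                           quad_order = NULL) {
  firing <- firing_params(1, 1, 0)  # placeholder; kappa taken as 1 below
  conn <- connectivity_params(kJ1, kJ2, sigma1, sigma2)
  params <- model_params(firing, conn, delay)
  eq <- structure(list(u_hat = NA_real_, kappa = 1,
                       w0 = total_kernel_mass(conn), residual = 0),
                  class = "equilibrium")
  new_linctx(params, eq, n_max, quad_order, "lumped-gain context (kappa = 1)")
}

# quadrature rule for degree n: base weights b_k (everything except the
# delay exponential) and delays tau_k, so G_n(lam) = sum(b * exp(-lam*tau))
ctx_rule <- function(ctx, n, order = ctx$quad_order) {
  key <- paste0(n, ":", order)
  r <- ctx$cache[[key]]
  if (is.null(r)) {
    gl <- gauss_theta_rule(order)
    th <- gl$x
    conn <- ctx$connectivity
    wker <- conn$J1 * exp(-th / conn$sigma1) + conn$J2 * exp(-th / conn$sigma2)
    r <- list(b = 2 * pi * gl$w * sin(th) * wker * legendre_polynomial(n, cos(th)),
              tau = ctx$delay$tau0 + th / ctx$delay$c)
    ctx$cache[[key]] <- r
  }
  r
}

choose_quad_order <- function(ctx, tol = 1e-11) {
  # most oscillatory point of the default search box
  lam_ref <- -6 + 1i * (2 * pi / ctx$delay$h + 10)
  order <- 64L
  gval <- function(n, order) {
    r <- ctx_rule(ctx, n, order)
    sum(r$b * exp(-lam_ref * r$tau))
  }
  degs <- unique(c(0L, ctx$n_max))
  repeat {
    ok <- all(vapply(degs, function(n) {
      abs(gval(n, order) - gval(n, 2L * order)) <= tol * max(1, abs(gval(n, 2L * order)))
    }, logical(1)))
    if (ok) return(2L * order)
    order <- 2L * order
    if (order > 2^13) return(2^14)
  }
}

#' Kernel coefficients of the linearization
#'
#' `G_n` evaluates the Funk-Hecke coefficient of the delayed kernel
#' \eqn{w(s) e^{-\lambda \tau(s)}}; `G_n_prime` its derivative in
#' \eqn{\lambda} (the transform of \eqn{-\tau(s) w(s) e^{-\lambda\tau(s)}}).
#' `E_n` is the characteristic function
#' \eqn{E_n(\lambda) = \lambda + 1 - \kappa G_n(\lambda)} whose roots are the
#' point spectrum of the linearized field at degree `n` (each with
#' multiplicity \eqn{2n+1}); the essential spectrum is the single point
#' \eqn{\lambda = -1}.
#'
#' @param ctx A [linearization_context()].
#' @param n Degree.
#' @param lam Complex spectral parameter (vectorized).
#' @return Complex vector.
#' @export
G_n <- function(ctx, n, lam) {
  r <- ctx_rule(ctx, n)
  vapply(lam, function(l) sum(r$b * exp(-l * r$tau)), complex(1))
}

#' @rdname G_n
#' @export
G_n_prime <- function(ctx, n, lam) {
  r <- ctx_rule(ctx, n)
  vapply(lam, function(l) sum(-r$tau * r$b * exp(-l * r$tau)), complex(1))
}

#' @rdname G_n
#' @export
E_n <- function(ctx, n, lam) {
  lam + 1 - ctx$kappa * G_n(ctx, n, lam)
}

E_n_prime <- function(ctx, n, lam) {
  1 - ctx$kappa * G_n_prime(ctx, n, lam)
}

#' Default eigenvalue search box
#'
#' Rectangle \eqn{\mathrm{Re} \in [-6, 2]},
#' \eqn{\mathrm{Im} \in [0, 2\pi/h + 10]} with \eqn{h} the maximal delay:
#' delay-induced root branches accumulate leftward and the box covers the
#' rightmost branches that decide stability. Roots in the lower half-plane
#' follow by conjugate symmetry.
#'
#' @param ctx A [linearization_context()].
#' @return List with `re` and `im` ranges.
#' @export
default_box <- function(ctx) {
  list(re = c(-6, 2), im = c(0, 2 * pi / ctx$delay$h + 10))
}

#' Eigenvalues of one harmonic degree
#'
#' Finds all roots of \eqn{E_n(\lambda) = 0} inside a rectangular search box
#' by Newton iteration (using the analytic derivative) started from a uniform
#' seed grid, followed by residual filtering, deduplication and conjugate
#' completion. The count can be certified independently with
#' [winding_count()] (argument principle on the box boundary).
#'
#' @param ctx A [linearization_context()].
#' @param n Degree.
#' @param box Search rectangle, `list(re = c(lo, hi), im = c(lo, hi))`.
#'   Boxes are interpreted in the closed upper half-plane; if `im[1] < 0`
#'   the box is assumed conjugate-symmetric and only its upper half is
#'   searched, with conjugates of non-real roots appended.
#' @param grid Seed grid resolution per axis (default 25).
#' @param residual_tol Maximum certified residual: \eqn{|E_n(\lambda)|}
#'   scaled by the magnitude of its evaluation (a backward-error measure;
#'   equal to the plain absolute residual for roots near the imaginary
#'   axis, where the evaluation magnitude is order one).
#' @param max_iter Newton iteration cap.
#' @param verify Check the root count against the boundary winding number
#'   and refine the seed grid (up to two doublings) on disagreement; an
#'   unresolved mismatch is an error.
#' @return A data frame with columns `n`, `lam` (complex) and `residual`,
#'   sorted by decreasing real part. Zero rows if the degree has no roots in
#'   the box. An error is raised if no Newton start converges at all.
#' @export
solve_modes <- function(ctx, n, box = default_box(ctx), grid = 25L,
                        residual_tol = 1e-9, max_iter = 80L, verify = FALSE) {
  if (verify) {
    expected <- winding_count(ctx, n, box)
    for (g in grid * c(1L, 2L, 4L)) {
      out <- solve_modes(ctx, n, box, grid = g, residual_tol = residual_tol,
                         max_iter = max_iter, verify = FALSE)
      if (nrow(out) == expected) return(out)
    }
    stop("root count ", nrow(out), " does not match the winding number ",
         expected, " for degree ", n)
  }
  re <- sort(box$re)
  im <- sort(box$im)
  if (diff(re) <= 0) stop("search box must have positive width in Re")
  conj_box <- im[1] < 0
  im_lo <- max(0, im[1])
  seeds <- as.vector(outer(seq(re[1], re[2], length.out = grid),
                           1i * seq(im_lo, im[2], length.out = grid), `+`))
  lam <- seeds
  done <- complex(0)
  for (it in seq_len(max_iter)) {
    E <- E_n(ctx, n, lam)
    Ep <- E_n_prime(ctx, n, lam)
    step <- E / Ep
    lam <- lam - step
    # discard runaways to keep the exp() evaluations bounded
    bad <- !is.finite(lam) | Re(lam) < re[1] - 8 | Re(lam) > re[2] + 8 |
      abs(Im(lam)) > abs(im[2]) + 20
    conv <- !bad & abs(step) < 1e-13
    done <- c(done, lam[conv])
    lam <- lam[!bad & !conv]
    if (!length(lam)) break
  }
  lam <- c(done, lam)
  if (!length(lam)) {
    stop("Newton iterations failed to converge from every seed; no verdict ",
         "(distinguish from an argument-principle count of zero)")
  }
  resid <- abs(E_n(ctx, n, lam))
  keep <- resid <= residual_tol &
    Re(lam) >= re[1] - 1e-10 & Re(lam) <= re[2] + 1e-10 &
    Im(lam) >= im_lo - 1e-10 & Im(lam) <= im[2] + 1e-10
  lam <- lam[keep]
  # canonicalize: tiny imaginary parts are real roots
  lam[abs(Im(lam)) < 1e-10] <- complex(real = Re(lam[abs(Im(lam)) < 1e-10]), imaginary = 0)
  roots <- complex(0)
  for (l in lam[order(Re(lam), Im(lam))]) {
    if (!length(roots) || min(Mod(roots - l)) > 1e-6) roots <- c(roots, l)
  }
  if (conj_box) {
    roots <- c(roots, Conj(roots[Im(roots) > 1e-10]))
  }
  if (!length(roots)) {
    return(data.frame(n = integer(0), lam = complex(0), residual = numeric(0)))
  }
  # polish and certify on a doubled-order rule: for roots deep in the left
  # half-plane the integrand is exponentially large, so the base rule only
  # locates them to its own quadrature accuracy
  r2 <- ctx_rule(ctx, n, 2L * ctx$quad_order)
  for (k in 1:3) {
    E2 <- vapply(roots, function(l) l + 1 - ctx$kappa * sum(r2$b * exp(-l * r2$tau)), complex(1))
    Ep2 <- vapply(roots, function(l) 1 + ctx$kappa * sum(r2$tau * r2$b * exp(-l * r2$tau)), complex(1))
    roots <- roots - E2 / Ep2
  }
  # backward-error certificate: |E_n| relative to the magnitude of its
  # evaluation (terms grow like e^{|Re lam| h}, so an absolute bound is
  # unattainable deep in the left half-plane; near the imaginary axis the
  # scale is 1 and the certificate is the plain absolute residual)
  res2 <- vapply(roots, function(l) {
    terms <- r2$b * exp(-l * r2$tau)
    scale <- max(1, Mod(l) + 1 + abs(ctx$kappa) * sum(Mod(terms)))
    abs(l + 1 - ctx$kappa * sum(terms)) / scale
  }, numeric(1))
  keep2 <- res2 <= residual_tol
  roots <- roots[keep2]
  res2 <- res2[keep2]
  if (!length(roots)) {
    return(data.frame(n = integer(0), lam = complex(0), residual = numeric(0)))
  }
  out <- data.frame(n = rep.int(as.integer(n), length(roots)),
                    lam = roots, residual = res2)
  out[order(-Re(out$lam), abs(Im(out$lam))), , drop = FALSE]
}

#' Argument-principle root count on a box boundary
#'
#' Counts zeros of \eqn{E_n} inside the rectangle by accumulating the phase
#' winding of \eqn{E_n} along the boundary, with adaptive refinement of
#' segments whose phase increment exceeds \eqn{\pi/2}. `E_n` is entire, so
#' the winding number equals the number of enclosed roots (with
#' multiplicity).
#'
#' @param ctx A [linearization_context()].
#' @param n Degree.
#' @param box Rectangle as in [solve_modes()] (used verbatim; pass the full
#'   conjugate box to count conjugate pairs).
#' @param pts_per_side Initial boundary sampling per side.
#' @return Integer winding number.
#' @export
winding_count <- function(ctx, n, box, pts_per_side = 200L) {
  re <- sort(box$re)
  im <- sort(box$im)
  corners <- c(complex(real = re[1], imaginary = im[1]),
               complex(real = re[2], imaginary = im[1]),
               complex(real = re[2], imaginary = im[2]),
               complex(real = re[1], imaginary = im[2]),
               complex(real = re[1], imaginary = im[1]))
  pts <- unlist(lapply(1:4, function(k) {
    t <- seq(0, 1, length.out = pts_per_side + 1L)[-(pts_per_side + 1L)]
    corners[k] + t * (corners[k + 1L] - corners[k])
  }))
  pts <- c(pts, pts[1])
  vals <- E_n(ctx, n, pts)
  total <- 0
  i <- 1L
  while (i < length(pts)) {
    d <- Arg(vals[i + 1L] / vals[i])
    if (abs(d) > pi / 2) {
      # refine this segment
      sub <- pts[i] + seq(0, 1, length.out = 17L) * (pts[i + 1L] - pts[i])
      sv <- E_n(ctx, n, sub)
      d <- sum(Arg(sv[-1] / sv[-length(sv)]))
    }
    total <- total + d
    i <- i + 1L
  }
  as.integer(round(total / (2 * pi)))
}

#' Rightmost eigenvalue over all degrees
#'
#' Scans degrees \eqn{n = 0, \dots, n_{max}} with [solve_modes()] over the
#' default box and returns the eigenvalue of maximal real part; ties are
#' broken by smaller degree, then smaller \eqn{|\mathrm{Im}|}. The steady
#' state is asymptotically stable iff the returned real part is negative
#' (the essential spectrum sits at \eqn{-1}).
#'
#' @param ctx A [linearization_context()].
#' @param box Search box (default [default_box()]).
#' @param grid Seed grid resolution passed to [solve_modes()].
#' @return One-row data frame (`n`, `lam`, `residual`).
#' @export
rightmost_eigenvalue <- function(ctx, box = default_box(ctx), grid = 25L) {
  best <- NULL
  for (n in 0:ctx$n_max) {
    ev <- solve_modes(ctx, n, box, grid = grid)
    if (!nrow(ev)) next
    cand <- ev[1L, ]
    if (is.null(best) ||
        Re(cand$lam) > Re(best$lam) + 1e-12 ||
        (abs(Re(cand$lam) - Re(best$lam)) <= 1e-12 &&
         (cand$n < best$n ||
          (cand$n == best$n && abs(Im(cand$lam)) < abs(Im(best$lam)))))) {
      best <- cand
    }
  }
  if (is.null(best)) stop("no eigenvalues found in the search box")
  best
}

#' Full spectrum over degrees
#'
#' Convenience wrapper collecting [solve_modes()] for all degrees up to
#' `n_max` into one table (columns `n`, `lam`, `residual`), closed under
#' conjugation when the box includes the lower half-plane.
#'
#' @param ctx A [linearization_context()].
#' @param box Search box.
#' @param n_max Degree cap (default `ctx$n_max`).
#' @return Object of class `spectrum`: the data frame plus attributes
#'   `essential_point` (-1) and `box`.
#' @export
compute_spectrum <- function(ctx, box = default_box(ctx), n_max = ctx$n_max) {
  evs <- do.call(rbind, lapply(0:n_max, function(n) solve_modes(ctx, n, box)))
  structure(evs, essential_point = -1 + 0i, box = box,
            class = c("spectrum", class(evs)))
}

#' Export a spectrum as a plain table
#'
#' @param spectrum A `spectrum` (or `solve_modes` result).
#' @return Data frame with columns `n`, `re`, `im`, `residual`.
#' @export
spectrum_table <- function(spectrum) {
  data.frame(n = spectrum$n, re = Re(spectrum$lam), im = Im(spectrum$lam),
             residual = spectrum$residual)
}

#' Resolvent applied degree-wise to a harmonic expansion
#'
#' For a regular value \eqn{\mu} (no characteristic equation vanishes), the
#' resolvent of the linearization acts diagonally on harmonics:
#' \eqn{q_{nm} = y_{nm} / (\mu + 1 - \kappa G_n(\mu))}.
#'
#' @param y A `degree_spectrum` (right-hand side expansion).
#' @param mu Complex regular value.
#' @param ctx A [linearization_context()].
#' @param singular_tol Values of \eqn{|E_n(\mu)|} below this threshold are
#'   treated as (near-)singular and raise an error.
#' @return A `degree_spectrum` of the solution coefficients.
#' @export
resolvent_coefficients <- function(y, mu, ctx, singular_tol = 1e-8) {
  stopifnot(inherits(y, "degree_spectrum"))
  q <- y$coefficients
  for (n in 0:y$n_max) {
    en <- E_n(ctx, n, mu)
    if (abs(en) <= singular_tol) {
      stop("mu is within ", singular_tol, " of the point spectrum at degree ", n)
    }
    idx <- nm_index(n, -n:n)
    q[idx] <- y$coefficients[idx] / en
  }
  degree_spectrum(q, y$n_max)
}

#' Resolvent kernel ratio Q_n
#'
#' The helper \eqn{Q_n(\mu) = G_n(\mu) / (\mu + 1 - \kappa G_n(\mu))}
#' entering the cubic normal-form coefficient of the degree-0 Hopf
#' bifurcation (evaluated there at \eqn{\mu = 0} and \eqn{\mu = 2i\omega_0},
#' both regular by non-resonance).
#'
#' @param ctx A [linearization_context()].
#' @param n Degree.
#' @param mu Complex regular value.
#' @param singular_tol Near-singularity threshold on \eqn{|E_n(\mu)|}.
#' @return Complex scalar.
#' @export
Q_n <- function(ctx, n, mu, singular_tol = 1e-8) {
  g <- G_n(ctx, n, mu)
  en <- mu + 1 - ctx$kappa * g
  if (abs(en) <= singular_tol) {
    stop("mu is within ", singular_tol, " of the point spectrum at degree ", n)
  }
  g / en
}
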