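#' Firing-rate parameters
#'
#' Parameters of the sigmoidal firing-rate function
#' \eqn{f(u) = \alpha / (1 + e^{-\beta(u - \delta)})}.
#'
#' @param alpha Maximal firing rate, \eqn{\alpha > 0}.
#' @param beta Steepness of the sigmoid, \eqn{\beta > 0}.
#' @param delta Firing threshold (inflection point of the sigmoid).
#'
#' @return An object of class `firing_params`.
#' @export
#' @examples
#' fp <- firing_params(alpha = 1, beta = 8, delta = 0)
#' firing_rate(0, fp) # alpha/2 at threshold
firing_params <- function(alpha, beta, delta = 0) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0,
            is.numeric(beta), length(beta) == 1L, beta > 0,
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  structure(list(alpha = alpha, beta = beta, delta = delta),
            class = "firing_params")
}

#' Connectivity-kernel parameters
#'
#' Parameters of the two-exponential rotation-invariant kernel
#' \eqn{w(s) = J_1 e^{-\arccos(s)/\sigma_1} + J_2 e^{-\arccos(s)/\sigma_2}}
#' where \eqn{s = r \cdot r'} is the cosine of the angular separation.
#' For \eqn{J_1 + J_2 > 0} the kernel has a wizard-hat shape (local
#' excitation, lateral inhibition when \eqn{J_2 < 0}); for
#' \eqn{J_1 + J_2 < 0} it is inverted.
#'
#' @param J1,J2 Amplitudes of the broad and narrow exponential respectively.
#' @param sigma1,sigma2 Angular decay scales in radians. The conventional
#'   ordering `sigma1 > sigma2 > 0` is expected; violation triggers a warning
#'   (not an error).
#'
#' @return An object of class `connectivity_params` with a `shape` label.
#' @export
connectivity_params <- function(J1, J2, sigma1, sigma2) {
  stopifnot(is.numeric(J1), is.numeric(J2), is.finite(J1), is.finite(J2),
            is.numeric(sigma1), sigma1 > 0, is.numeric(sigma2), sigma2 > 0)
  if (!(sigma1 > sigma2)) {
    warning("expected sigma1 > sigma2 > 0; proceeding with the given scales")
  }
  shape <- if (J1 + J2 > 0) "wizard-hat" else if (J1 + J2 < 0) "inverted" else "balanced-peak"
  structure(list(J1 = J1, J2 = J2, sigma1 = sigma1, sigma2 = sigma2,
                 shape = shape),
            class = "connectivity_params")
}

#' Transmission-delay parameters
#'
#' Parameters of the distance-dependent delay
#' \eqn{\tau(s) = \tau_0 + \arccos(s)/c}: a constant offset delay plus
#' great-circle distance divided by a finite propagation speed. The maximal
#' delay is \eqn{h = \tau_0 + \pi/c}, attained at antipodal points.
#'
#' @param tau0 Offset delay, \eqn{\tau_0 \ge 0} (time units).
#' @param c Propagation speed, \eqn{c > 0} (radians per time unit).
#'
#' @return An object of class `delay_params` with the maximal delay `h`.
#' @export
delay_params <- function(tau0, c) {
  stopifnot(is.numeric(tau0), length(tau0) == 1L, tau0 >= 0,
            is.numeric(c), length(c) == 1L, c > 0)
  structure(list(tau0 = tau0, c = c, h = tau0 + pi / c),
            class = "delay_params")
}

#' Full model parameter set
#'
#' @param firing A [firing_params()] object.
#' @param connectivity A [connectivity_params()] object.
#' @param delay A [delay_params()] object.
#'
#' @return An object of class `model_params`.
#' @export
model_params <- function(firing, connectivity, delay) {
  stopifnot(inherits(firing, "firing_params"),
            inherits(connectivity, "connectivity_params"),
            inherits(delay, "delay_params"))
  structure(list(firing = firing, connectivity = connectivity, delay = delay),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Spherical neural field parameters\n")
  cat(sprintf("  firing      : alpha=%g beta=%g delta=%g\n",
              x$firing$alpha, x$firing$beta, x$firing$delta))
  cat(sprintf("  connectivity: J1=%g J2=%g sigma1=%g sigma2=%g (%s)\n",
              x$connectivity$J1, x$connectivity$J2,
              x$connectivity$sigma1, x$connectivity$sigma2,
              x$connectivity$shape))
  cat(sprintf("  delay       : tau0=%g c=%g (max delay h=%g)\n",
              x$delay$tau0, x$delay$c, x$delay$h))
  invisible(x)
}

#' Serialize model parameters to/from flat JSON
#'
#' The flat document has keys `alpha, beta, delta, J1, J2, sigma1, sigma2,
#' tau0, c`.
#'
#' @param params A [model_params()] object.
#' @param path File path; if `NULL`, `params_to_json` returns the JSON string.
#' @return `params_to_json`: the path or JSON string, invisibly.
#'   `params_from_json`: a [model_params()] object.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "model_params"))
  doc <- list(alpha = params$firing$alpha, beta = params$firing$beta,
              delta = params$firing$delta,
              J1 = params$connectivity$J1, J2 = params$connectivity$J2,
              sigma1 = params$connectivity$sigma1,
              sigma2 = params$connectivity$sigma2,
              tau0 = params$delay$tau0, c = params$delay$c)
  if (is.null(path)) {
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @param json A JSON string, file path, or an already-parsed named list.
#' @export
params_from_json <- function(json) {
  doc <- if (is.list(json)) json else jsonlite::fromJSON(json)
  need <- c("alpha", "beta", "delta", "J1", "J2", "sigma1", "sigma2", "tau0", "c")
  miss <- setdiff(need, names(doc))
  if (length(miss)) stop("missing parameter keys: ", paste(miss, collapse = ", "))
  model_params(firing_params(doc$alpha, doc$beta, doc$delta),
               connectivity_params(doc$J1, doc$J2, doc$sigma1, doc$sigma2),
               delay_params(doc$tau0, doc$c))
}

#' Sigmoidal firing rate and its derivatives
#'
#' `firing_rate` evaluates \eqn{f(u) = \alpha/(1+e^{-\beta(u-\delta)})}
#' overflow-safely (it saturates to 0 or \eqn{\alpha} for large arguments and
#' never returns `NaN`). `firing_rate_derivative` returns the exact analytic
#' derivative of order 1, 2 or 3, needed by the linearization
#' (\eqn{\kappa = f'(\hat u)}) and by the cubic normal-form coefficient
#' (which involves \eqn{f''(\hat u)} and \eqn{f'''(\hat u)}).
#'
#' With \eqn{s = f(u)/\alpha} the logistic value, the derivatives are
#' \eqn{f' = \alpha\beta s(1-s)}, \eqn{f'' = \alpha\beta^2 s(1-s)(1-2s)},
#' \eqn{f''' = \alpha\beta^3 s(1-s)(1-6s+6s^2)}.
#'
#' @param u Membrane activity (vectorized).
#' @param p A [firing_params()] object.
#' @param order Derivative order, one of 1, 2, 3.
#' @return Numeric vector of the same length as `u`.
#' @export
firing_rate <- function(u, p) {
  stopifnot(inherits(p, "firing_params"))
  p$alpha * stats::plogis(p$beta * (u - p$delta))
}

#' @rdname firing_rate
#' @export
firing_rate_derivative <- function(u, p, order = 1L) {
  stopifnot(inherits(p, "firing_params"))
  if (!(length(order) == 1L && order %in% 1:3)) {
    stop("'order' must be 1, 2 or 3")
  }
  s <- stats::plogis(p$beta * (u - p$delta))
  base <- s * (1 - s)
  switch(order,
         p$alpha * p$beta * base,
         p$alpha * p$beta^2 * base * (1 - 2 * s),
         p$alpha * p$beta^3 * base * (1 - 6 * s + 6 * s^2))
}

# Clamp a cosine argument to [-1, 1]; values within `tol` outside the
# interval (floating-point dot products of unit vectors) are clamped,
# anything further out is an error.
clamp_cosine <- function(s, tol = 1e-12) {
  if (any(!is.finite(s)) || any(s < -1 - tol) || any(s > 1 + tol)) {
    stop("cosine argument outside [-1, 1] beyond tolerance ", tol)
  }
  s[s > 1] <- 1
  s[s < -1] <- -1
  s
}

#' Connectivity kernel and delay as functions of cosine separation
#'
#' `kernel_profile` evaluates
#' \eqn{w(s) = J_1 e^{-\arccos(s)/\sigma_1} + J_2 e^{-\arccos(s)/\sigma_2}},
#' `delay_profile` evaluates \eqn{\tau(s) = \tau_0 + \arccos(s)/c}, where
#' \eqn{s = r\cdot r' \in [-1,1]}. Arguments within `1e-12` of the interval
#' bounds are clamped (unit-vector dot products routinely overshoot by a few
#' ulp); anything further out is rejected.
#'
#' @param s Cosine of angular separation, in \eqn{[-1, 1]} (vectorized).
#' @param p A [connectivity_params()] (for `kernel_profile`) or
#'   [delay_params()] (for `delay_profile`) object.
#' @return Numeric vector.
#' @export
kernel_profile <- function(s, p) {
  stopifnot(inherits(p, "connectivity_params"))
  th <- acos(clamp_cosine(s))
  p$J1 * exp(-th / p$sigma1) + p$J2 * exp(-th / p$sigma2)
}

#' @rdname kernel_profile
#' @export
delay_profile <- function(s, p) {
  stopifnot(inherits(p, "delay_params"))
  p$tau0 + acos(clamp_cosine(s)) / p$c
}

#' Total kernel mass
#'
#' The degree-0 Funk-Hecke coefficient of the connectivity kernel,
#' \eqn{w_0 = 2\pi \int_{-1}^1 w(s)\,ds}. A kernel with \eqn{w_0 = 0} is
#' called balanced; it forces the zero homogeneous equilibrium.
#'
#' @param connectivity A [connectivity_params()] object.
#' @return Scalar kernel mass.
#' @export
total_kernel_mass <- function(connectivity) {
  stopifnot(inherits(connectivity, "connectivity_params"))
  Re(connectivity$J1 * hn_coefficient(0, 0, connectivity$sigma1, delay_params(0, 1)) +
       connectivity$J2 * hn_coefficient(0, 0, connectivity$sigma2, delay_params(0, 1)))
}

new_equilibrium <- function(u_hat, firing, w0, residual) {
  structure(list(u_hat = u_hat,
                 kappa = firing_rate_derivative(u_hat, firing, 1L),
                 w0 = w0, residual = residual),
            class = "equilibrium")
}

#' @export
print.equilibrium <- function(x, ...) {
  cat(sprintf("homogeneous equilibrium: u_hat=%.10g kappa=%.10g w0=%.10g (residual %.2e)\n",
              x$u_hat, x$kappa, x$w0, x$residual))
  invisible(x)
}

#' Homogeneous equilibria of the field
#'
#' Finds all real roots of \eqn{\hat u = w_0 f(\hat u)}, the fixed-point
#' condition for spatially homogeneous steady states. Because \eqn{f} is
#' bounded, all roots lie in \eqn{[-|w_0|\alpha - 1, |w_0|\alpha + 1]}; the
#' interval is scanned on a uniform grid and every sign change bisected. For
#' the sigmoid firing rate at most three equilibria can occur; a balanced
#' kernel (\eqn{w_0 = 0}) forces the unique equilibrium \eqn{\hat u = 0}.
#' Near-tangencies (local minima of the residual below `fold_tol` without a
#' sign change) are reported in the `fold_candidates` attribute.
#'
#' @param params A [model_params()] object.
#' @param n_grid Number of bracketing sub-intervals (default 2048).
#' @param tol Root tolerance passed to the bisection polish.
#' @param fold_tol Residual threshold flagging a near-tangency (fold point).
#' @return A list of `equilibrium` objects sorted by increasing
#'   \eqn{\hat u}, with attribute `fold_candidates`.
#' @export
find_equilibria <- function(params, n_grid = 2048L, tol = 1e-13,
                            fold_tol = 1e-8) {
  stopifnot(inherits(params, "model_params"))
  w0 <- total_kernel_mass(params$connectivity)
  g <- function(u) u - w0 * firing_rate(u, params$firing)
  lo <- -abs(w0) * params$firing$alpha - 1
  hi <- abs(w0) * params$firing$alpha + 1
  us <- seq(lo, hi, length.out = n_grid + 1L)
  gs <- g(us)
  roots <- numeric(0)
  exact <- which(gs == 0)
  roots <- c(roots, us[exact])
  sgn <- which(gs[-1] * gs[-length(gs)] < 0)
  for (i in sgn) {
    r <- stats::uniroot(g, c(us[i], us[i + 1L]), tol = tol)$root
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  # near-tangency scan: interior local minima of |g| without sign change
  folds <- numeric(0)
  ag <- abs(gs)
  loc <- which(diff(sign(diff(ag))) > 0) + 1L
  for (i in loc) {
    if (ag[i] < fold_tol && (!length(roots) || min(abs(roots - us[i])) > (hi - lo) / n_grid)) {
      folds <- c(folds, us[i])
    }
  }
  out <- lapply(roots, function(r) {
    new_equilibrium(r, params$firing, w0, abs(g(r)))
  })
  attr(out, "fold_candidates") <- folds
  out
}

#' Calibrate raw coupling amplitudes to target lumped gains
#'
#' Bifurcation diagrams for the linearized field are naturally drawn in the
#' lumped coordinates \eqn{(\kappa J_1, \kappa J_2)} where
#' \eqn{\kappa = f'(\hat u)}, but the simulator needs raw amplitudes
#' \eqn{(J_1, J_2)}. Since \eqn{\hat u} itself depends on \eqn{(J_1, J_2)}
#' through the kernel mass, the triple \eqn{(J_1, J_2, \hat u)} must be solved
#' jointly:
#' \deqn{\kappa(\hat u) J_i = t_i, \qquad \hat u = w_0(J_1, J_2) f(\hat u).}
#' The system reduces to a scalar root-find in \eqn{\hat u}: given targets
#' \eqn{t_i}, \eqn{J_i(\hat u) = t_i / f'(\hat u)} and the residual is
#' \eqn{\hat u - w_0(\hat u) f(\hat u)}.
#'
#' When several \eqn{\hat u} branches solve the system, the branch whose
#' leading degree-0 eigenvalue pair lies closest to the imaginary axis is
#' selected (the destabilizing branch); all branches are returned in the
#' `branches` attribute.
#'
#' @param target_kJ1,target_kJ2 Target lumped gains \eqn{\kappa J_1},
#'   \eqn{\kappa J_2} (not both zero).
#' @param firing A [firing_params()] object.
#' @param sigmas Length-2 numeric, the kernel scales `c(sigma1, sigma2)`.
#' @param delay A [delay_params()] object.
#' @param residual_tol Acceptance tolerance on the joint residuals.
#' @return A list with elements `connectivity` ([connectivity_params()]),
#'   `equilibrium` (`equilibrium`), `params` (full [model_params()]) and
#'   `residuals`; attribute `branches` holds all solutions found.
#' @export
calibrate_couplings <- function(target_kJ1, target_kJ2, firing, sigmas, delay,
                                residual_tol = 1e-10) {
  stopifnot(inherits(firing, "firing_params"), inherits(delay, "delay_params"),
            length(sigmas) == 2L, all(sigmas > 0))
  if (target_kJ1 == 0 && target_kJ2 == 0) {
    stop("targets must not both be zero")
  }
  h01 <- Re(hn_coefficient(0, 0, sigmas[1], delay_params(0, 1)))
  h02 <- Re(hn_coefficient(0, 0, sigmas[2], delay_params(0, 1)))
  lump <- target_kJ1 * h01 + target_kJ2 * h02  # = kappa * w0
  res <- function(u) {
    kap <- firing_rate_derivative(u, firing, 1L)
    u - (lump / kap) * firing_rate(u, firing)
  }
  b <- firing$beta
  span <- 50 / b
  lo <- min(firing$delta - span, lump / b - 1) - 1
  hi <- max(firing$delta + span, abs(lump) + 1) + 1
  us <- seq(lo, hi, length.out = 4001L)
  rs <- res(us)
  roots <- numeric(0)
  sgn <- which(is.finite(rs[-1]) & is.finite(rs[-length(rs)]) &
                 rs[-1] * rs[-length(rs)] < 0)
  for (i in sgn) {
    roots <- c(roots, stats::uniroot(res, c(us[i], us[i + 1L]), tol = 1e-14)$root)
  }
  if (!length(roots)) stop("calibration failed: no consistent equilibrium found")
  branches <- lapply(roots, function(u) {
    kap <- firing_rate_derivative(u, firing, 1L)
    conn <- connectivity_params(target_kJ1 / kap, target_kJ2 / kap,
                                sigmas[1], sigmas[2])
    pars <- model_params(firing, conn, delay)
    w0 <- total_kernel_mass(conn)
    eq <- new_equilibrium(u, firing, w0, abs(u - w0 * firing_rate(u, firing)))
    r2 <- abs(c(eq$kappa * conn$J1 - target_kJ1, eq$kappa * conn$J2 - target_kJ2))
    list(connectivity = conn, equilibrium = eq, params = pars,
         residuals = c(equilibrium = eq$residual, gains = max(r2)))
  })
  bad <- vapply(branches, function(bb) max(bb$residuals) > residual_tol, logical(1))
  if (all(bad)) stop("calibration did not converge below tolerance ", residual_tol)
  branches <- branches[!bad]
  sel <- 1L
  if (length(branches) > 1L) {
    # destabilizing-branch rule: leading degree-0 eigenvalue closest to the
    # imaginary axis
    dist <- vapply(branches, function(bb) {
      ctx <- linearization_context(bb$params, bb$equilibrium, n_max = 0L)
      ev <- tryCatch(rightmost_eigenvalue(ctx), error = function(e) NULL)
      if (is.null(ev)) Inf else abs(Re(ev$lam))
    }, numeric(1))
    sel <- which.min(dist)
  }
  out <- branches[[sel]]
  attr(out, "branches") <- branches
  out
}
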