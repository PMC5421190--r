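#' Dense delayed-coupling matrices on a mesh
#'
#' Precomputes the discretized kernel \eqn{W_{ij} = w(r_i \cdot r_j) w_j}
#' (quadrature weight folded into the column) and the pairwise delay matrix
#' \eqn{\tau_{ij} = \tau(r_i \cdot r_j)}, so that the delayed integral of
#' the field equation becomes
#' \eqn{\Phi_i(t) = \sum_j W_{ij}\, f(u(t - \tau_{ij}, r_j))}.
#'
#' The kernel has a derivative discontinuity at zero separation, which
#' plain vertex-weight quadrature resolves poorly for narrow kernels. With
#' `correct_rowsum = TRUE` (default) the self-coupling entry of each row is
#' adjusted so that the row sum equals the exact kernel mass \eqn{w_0}
#' (a near-field product-integration correction). This removes the leading
#' quadrature error of every modal gain and makes any homogeneous
#' equilibrium \eqn{\hat u = w_0 f(\hat u)} an exact fixed point of the
#' discretized operator; the uncorrected raw row-sum defect is kept in
#' `rowsum_defect` for diagnostics.
#'
#' @param mesh A [build_icosphere()] mesh.
#' @param params A [model_params()] object.
#' @param correct_rowsum Apply the diagonal row-sum correction.
#' @return Object of class `delayed_coupling`: `W`, `tau`, `max_delay`,
#'   `mesh`, `params`, `rowsum_defect`.
#' @export
delayed_coupling <- function(mesh, params, correct_rowsum = TRUE) {
  stopifnot(inherits(mesh, "sphere_mesh"), inherits(params, "model_params"))
  S <- clamp_cosine(tcrossprod(mesh$vertices))
  W <- kernel_profile(S, params$connectivity)
  W <- sweep(W, 2L, mesh$weights, `*`)
  defect <- total_kernel_mass(params$connectivity) - rowSums(W)
  if (correct_rowsum) diag(W) <- diag(W) + defect
  tau <- delay_profile(S, params$delay)
  structure(list(W = W, tau = tau, max_delay = params$delay$h,
                 mesh = mesh, params = params, rowsum_defect = defect),
            class = "delayed_coupling")
}

#' Simulation configuration
#'
#' @param dt Time step. Defaults to `0.05`; it is additionally capped at
#'   `h/10` (a tenth of the maximal delay) and, when `tau0 > 0`, at
#'   `tau0/2` so that every delayed lookup reaches at least one fully
#'   computed past step (the scheme stays explicit).
#' @param t_end Final time.
#' @param level Icosphere subdivision level (ignored if a mesh is passed to
#'   [simulate_field()] directly).
#' @param save_every Record diagnostics every this many steps.
#' @param n_max Maximum harmonic degree tracked in the diagnostics.
#' @param history Initial history specification over \eqn{[-h, 0]}, one of
#'   [history_constant()], [history_harmonic()], [history_random()], or a
#'   `function(t)` returning the field at time `t <= 0`.
#' @param seed RNG seed used by random history perturbations.
#' @param keep_fields If `TRUE`, store the full field at every save time.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.05, t_end = 100, level = 3L, save_every = 10L,
                       n_max = 8L, history = history_constant(0), seed = 1L,
                       keep_fields = FALSE) {
  stopifnot(dt > 0, t_end > 0, save_every >= 1)
  structure(list(dt = dt, t_end = t_end, level = as.integer(level),
                 save_every = as.integer(save_every), n_max = as.integer(n_max),
                 history = history, seed = as.integer(seed),
                 keep_fields = keep_fields),
            class = "sim_config")
}

#' Initial-history specifications
#'
#' `history_constant` holds the field at a constant value over the whole
#' delay interval (the default for equilibrium checks).
#' `history_harmonic` adds `amplitude * Re Y_n^m` to a base level.
#' `history_random` adds i.i.d. Gaussian noise per vertex (drawn once, held
#' constant in time, with the configured seed).
#'
#' @param value,base Constant field level (typically an equilibrium
#'   \eqn{\hat u}).
#' @param amplitude Perturbation amplitude.
#' @param n,m Harmonic degree and order of the perturbation.
#' @return A history specification list.
#' @export
history_constant <- function(value) {
  list(type = "constant", value = value)
}

#' @rdname history_constant
#' @export
history_harmonic <- function(base, amplitude, n, m) {
  list(type = "harmonic", base = base, amplitude = amplitude,
       n = as.integer(n), m = as.integer(m))
}

#' @rdname history_constant
#' @export
history_random <- function(base, amplitude) {
  list(type = "random", base = base, amplitude = amplitude)
}

build_history_field <- function(history, mesh, seed) {
  N <- nrow(mesh$vertices)
  if (is.function(history)) return(NULL) # handled per-snapshot
  switch(history$type,
         constant = rep(history$value, N),
         harmonic = {
           Y <- mesh_harmonics(mesh, history$n)
           history$base + history$amplitude *
             Re(Y[, nm_index(history$n, history$m)])
         },
         random = {
           set.seed(seed)
           history$base + history$amplitude * stats::rnorm(N)
         },
         stop("unknown history type"))
}

#' Direct simulation of the delayed neural field on a mesh
#'
#' Integrates
#' \deqn{\partial_t u(t, r_i) = -u(t, r_i) +
#'   \sum_j W_{ij} f(u(t - \tau_{ij}, r_j))}
#' with Heun (explicit trapezoidal) steps on a uniform grid. The firing-rate
#' history \eqn{f(u)} is kept in a ring buffer at step resolution and looked
#' up with linear interpolation in time; because the per-pair lag indices
#' are constant, every right-hand side reduces to two gathers and a dense
#' row sum. A `NaN`/blow-up guard aborts with the last finite state; a
#' history that does not span the maximal delay is a hard error.
#'
#' @param params A [model_params()] object.
#' @param config A [sim_config()].
#' @param mesh Optional prebuilt mesh (otherwise `config$level` is used).
#' @param coupling Optional prebuilt [delayed_coupling()] (reusable across
#'   runs with the same mesh and parameters).
#' @return Object of class `field_trajectory`: `times`, `mean` (spatial
#'   mean), `power` (saved times x degrees 0..n_max), `com` (x 3),
#'   `field_final`, optionally `fields`, plus `params`, `config`, `mesh`
#'   and the `completed` flag (`FALSE` if the blow-up guard fired).
#' @export
simulate_field <- function(params, config, mesh = NULL, coupling = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(config, "sim_config"))
  if (is.null(mesh)) mesh <- build_icosphere(config$level)
  if (is.null(coupling)) coupling <- delayed_coupling(mesh, params)
  N <- nrow(mesh$vertices)
  h <- coupling$max_delay
  dt <- min(config$dt, h / 10)
  if (params$delay$tau0 > 0) dt <- min(dt, params$delay$tau0 / 2)
  n_steps <- ceiling(config$t_end / dt)
  L <- ceiling(h / dt) + 3L  # ring-buffer length (snapshots)

  K <- floor(coupling$tau / dt)
  frac <- coupling$tau / dt - K
  if (max(K) + 1L >= L) stop("history buffer shorter than the maximal delay")
  A1 <- coupling$W * (1 - frac)
  A2 <- coupling$W * frac
  COL <- matrix(rep(seq_len(N), each = N), N, N)  # COL[i,j] = j

  fp <- params$firing
  fbuf <- matrix(0, N, L)   # firing-rate snapshots f(u(t_k))
  # fill history over [-h, 0]
  if (is.function(config$history)) {
    for (k in 0:(L - 1L)) {
      tk <- -k * dt
      u_k <- config$history(tk)
      if (length(u_k) != N) stop("history function must return one value per vertex")
      slot <- ((-k) %% L) + 1L
      fbuf[, slot] <- firing_rate(u_k, fp)
      if (k == 0L) u <- u_k
    }
  } else {
    u0 <- build_history_field(config$history, mesh, config$seed)
    fbuf[] <- firing_rate(u0, fp)
    u <- u0
  }

  phi_at <- function(step_idx) {
    sl <- (step_idx - K) %% L          # N x N matrix of slots (0-based)
    M1 <- matrix(fbuf[COL + N * sl], N, N)
    sl2 <- (step_idx - K - 1L) %% L
    M2 <- matrix(fbuf[COL + N * sl2], N, N)
    rowSums(A1 * M1 + A2 * M2)
  }

  n_saves <- floor(n_steps / config$save_every) + 1L
  times <- numeric(n_saves)
  means <- numeric(n_saves)
  power <- matrix(NA_real_, n_saves, config$n_max + 1L)
  coeffs <- matrix(NA_complex_, n_saves, (config$n_max + 1L)^2)
  com <- matrix(NA_real_, n_saves, 3L)
  fields <- if (config$keep_fields) matrix(NA_real_, n_saves, N) else NULL
  Y <- mesh_harmonics(mesh, config$n_max)
  wts <- mesh$weights
  record <- function(row, t, u) {
    times[row] <<- t
    means[row] <<- sum(wts * u) / (4 * pi)
    v <- as.vector(crossprod(Conj(Y), wts * u))
    coeffs[row, ] <<- v
    power[row, ] <<- vapply(0:config$n_max, function(n) {
      sum(Mod(v[nm_index(n, -n:n)])^2)
    }, numeric(1))
    com[row, ] <<- as.vector(crossprod(mesh$vertices, wts * u))
    if (config$keep_fields) fields[row, ] <<- u
  }
  record(1L, 0, u)
  save_row <- 1L
  completed <- TRUE

  for (step in seq_len(n_steps)) {
    # Heun: predictor with Phi at t, corrector with Phi at t+dt using the
    # predictor's firing rates
    phi0 <- phi_at(step - 1L)
    k1 <- -u + phi0
    u_pred <- u + dt * k1
    slot_new <- (step %% L) + 1L
    fbuf[, slot_new] <- firing_rate(u_pred, fp)
    phi1 <- phi_at(step)
    k2 <- -u_pred + phi1
    u_new <- u + dt / 2 * (k1 + k2)
    if (!all(is.finite(u_new)) || max(abs(u_new)) > 1e6) {
      completed <- FALSE
      warning("blow-up detected at t = ", step * dt,
              "; returning the last finite state")
      break
    }
    u <- u_new
    fbuf[, slot_new] <- firing_rate(u, fp)
    if (step %% config$save_every == 0L) {
      save_row <- save_row + 1L
      record(save_row, step * dt, u)
    }
  }

  keep <- seq_len(save_row)
  structure(list(times = times[keep], mean = means[keep],
                 power = power[keep, , drop = FALSE],
                 coeffs = coeffs[keep, , drop = FALSE],
                 com = com[keep, , drop = FALSE],
                 field_final = u,
                 fields = if (config$keep_fields) fields[keep, , drop = FALSE],
                 params = params, config = config, mesh = mesh,
                 dt = dt, completed = completed),
            class = "field_trajectory")
}

#' @export
print.field_trajectory <- function(x, ...) {
  cat(sprintf("field trajectory: %d saved states to t = %.2f (dt = %g, level %d, %s)\n",
              length(x$times), max(x$times), x$dt, x$mesh$level,
              if (x$completed) "completed" else "aborted on blow-up"))
  pw <- colMeans(x$power[max(1, nrow(x$power) - 9):nrow(x$power), , drop = FALSE])
  cat("late-time degree power:", paste(sprintf("n%d=%.3g", seq_along(pw) - 1L, pw),
                                       collapse = " "), "\n")
  invisible(x)
}

#' Dominant harmonic degree of the post-transient pattern
#'
#' Averages the recorded degree powers over the last `window` fraction of
#' the trajectory, excluding degree 0 optionally, and returns the argmax.
#'
#' @param traj A `field_trajectory`.
#' @param window Fraction of the trajectory (from the end) to average.
#' @param exclude_zero Drop the homogeneous degree from the argmax.
#' @return List with `degree` and the averaged `power` vector.
#' @export
dominant_degree <- function(traj, window = 0.25, exclude_zero = FALSE) {
  n <- nrow(traj$power)
  rows <- seq.int(max(1L, ceiling(n * (1 - window))), n)
  pw <- colMeans(traj$power[rows, , drop = FALSE])
  degs <- seq_along(pw) - 1L
  if (exclude_zero) {
    pw0 <- pw[-1]
    deg <- degs[-1][which.max(pw0)]
  } else {
    deg <- degs[which.max(pw)]
  }
  list(degree = deg, power = stats::setNames(pw, paste0("n", degs)))
}

#' Leading eigenvalue of one harmonic mode of the discretized operator
#'
#' Projects the mesh-discretized delayed coupling operator onto the
#' zonal harmonic of degree `n` and Newton-solves the resulting scalar
#' characteristic equation \eqn{\lambda + 1 - \kappa g_n^{disc}(\lambda) = 0}
#' with \eqn{g_n^{disc}(\lambda)} the Rayleigh-quotient modal gain of
#' \eqn{W_{ij} e^{-\lambda \tau_{ij}}}. This is the growth rate the
#' simulator's spatial discretization actually realizes for that mode,
#' independent of time-stepping error; comparing it across mesh levels
#' measures quadrature convergence.
#'
#' @param coupling A [delayed_coupling()] object.
#' @param n Harmonic degree.
#' @param kappa Linearization gain \eqn{f'(\hat u)}.
#' @param lam0 Complex starting guess (e.g. the continuum eigenvalue).
#' @param tol Newton tolerance on the characteristic residual.
#' @return Complex eigenvalue of the semi-discrete linearization.
#' @export
discrete_mode_eigenvalue <- function(coupling, n, kappa, lam0, tol = 1e-12) {
  stopifnot(inherits(coupling, "delayed_coupling"))
  mesh <- coupling$mesh
  y <- mesh_harmonics(mesh, n)[, nm_index(n, 0)]
  wy <- mesh$weights * y
  den <- Re(sum(Conj(y) * wy))
  gd <- function(lam) {
    sum(Conj(wy) * ((coupling$W * exp(-lam * coupling$tau)) %*% y)) / den
  }
  lam <- lam0
  for (it in 1:60) {
    f <- lam + 1 - kappa * gd(lam)
    if (abs(f) < tol) break
    fp <- 1 - kappa * (gd(lam + 1e-6) - gd(lam)) / 1e-6
    lam <- lam - f / fp
  }
  if (abs(lam + 1 - kappa * gd(lam)) > 1e-8) {
    stop("discrete mode eigenvalue did not converge")
  }
  lam
}
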