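test_that("icosphere meshes satisfy the combinatorial and quadrature identities", {
  for (lev in 0:4) {
    m <- build_icosphere(lev)
    V <- nrow(m$vertices); F_ <- nrow(m$triangles); E <- V + F_ - 2
    expect_equal(F_, 20 * 4^lev)
    expect_equal(V, 10 * 4^lev + 2)
    expect_equal(V - E + F_, 2)                          # Euler characteristic
    expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 1)), 1e-12)
    expect_equal(sum(m$weights), 4 * pi, tolerance = 1e-13)
    expect_true(all(m$weights > 0))
  }
  m4 <- build_icosphere(4)
  expect_identical(nrow(m4$triangles), 5120L)            # figure-scale mesh
  expect_lt(abs(m4$raw_area / (4 * pi) - 1), 0.005)      # spherical-excess total
  expect_error(build_icosphere(8), "0..7")
})

test_that("center of mass vanishes for homogeneous fields and aligns for Y_1^0", {
  m <- build_icosphere(3)
  expect_lt(max(abs(center_of_mass(rep(2.7, nrow(m$vertices)), m))), 1e-10)
  f10 <- Re(spherefield:::mesh_harmonics(m, 1)[, spherefield:::nm_index(1, 0)])
  cm <- center_of_mass(f10, m)
  expect_lt(max(abs(cm[1:2])), 1e-8)
  # closed form: integral of sqrt(3/4pi) cos(theta) * z over the sphere
  expect_equal(cm[3], sqrt(4 * pi / 3), tolerance = 1e-4)
})

test_that("delayed coupling matrices satisfy symmetry, delay bounds and row sums", {
  m <- build_icosphere(2)
  conn <- connectivity_params(1.678, -4.367, 1, 0.5)
  pars <- model_params(firing_params(1, 4, 0.1), conn, delay_params(3, 1))
  cp <- delayed_coupling(m, pars, correct_rowsum = FALSE)
  # kernel symmetry up to the quadrature weights
  Wsym <- sweep(cp$W, 2L, m$weights, `/`)
  expect_lt(max(abs(Wsym - t(Wsym))), 1e-12)
  expect_equal(unname(diag(cp$tau)), rep(3, nrow(m$vertices)))
  expect_lte(max(cp$tau), 3 + pi / 1 + 1e-12)
  # row-sum correction reproduces the exact kernel mass
  cpc <- delayed_coupling(m, pars)
  expect_lt(max(abs(rowSums(cpc$W) - total_kernel_mass(conn))), 1e-12)
})

test_that("a homogeneous equilibrium is preserved to high precision", {
  cal <- calibrate_couplings(1.565, -4.075, firing_params(1, 4, 0.4172),
                             c(fix_hopf$sigma1, fix_hopf$sigma2), fix_hopf$delay)
  cfg <- sim_config(dt = 0.05, t_end = 15, level = 2, save_every = 50,
                    history = history_constant(cal$equilibrium$u_hat))
  tr <- simulate_field(cal$params, cfg)
  expect_true(tr$completed)
  expect_lt(max(abs(tr$field_final - cal$equilibrium$u_hat)), 1e-10)
})

test_that("simulated linear growth and frequency match the spectral eigenvalue", {
  # balanced Hopf couplings pushed past the bifurcation by raising the
  # firing-rate ceiling: a clearly unstable degree-0 pair
  cal <- calibrate_couplings(1.565384, -4.074967, firing_params(1, 4, 0.4172),
                             c(fix_hopf$sigma1, fix_hopf$sigma2), fix_hopf$delay)
  pars <- model_params(firing_params(1.2, 4, 0.4172), cal$connectivity,
                       fix_hopf$delay)
  ctx <- linearization_context(pars, n_max = 0)
  ev <- solve_modes(ctx, 0, list(re = c(-1, 1), im = c(0, 2)))
  lam <- ev$lam[1]
  eq <- ctx$equilibrium
  cfg <- sim_config(dt = 0.02, t_end = 80, level = 2, save_every = 2,
                    n_max = 1, history = history_harmonic(eq$u_hat, 1e-6, 0, 0))
  tr <- simulate_field(pars, cfg)
  dev <- tr$mean - eq$u_hat
  sel <- tr$times > 25
  x <- tr$times[sel]; d <- dev[sel]
  zc <- which(d[-1] * d[-length(d)] < 0)
  tc <- x[zc] - d[zc] * (x[zc + 1] - x[zc]) / (d[zc + 1] - d[zc])
  omega_meas <- pi / mean(diff(tc))
  y <- log(abs(d))
  pk <- which(diff(sign(diff(y))) < 0) + 1
  fit <- stats::lm(y[pk] ~ x[pk])
  growth_meas <- unname(stats::coef(fit)[2])
  expect_rel_equal(growth_meas, Re(lam), 0.05)
  expect_rel_equal(omega_meas, Im(lam), 0.05)
})

test_that("perturbations decay inside the stability region and grow outside", {
  dl <- fix_pattern$delay
  fir <- fix_pattern$firing
  pts <- list(stable = list(c(5, -15), c(-5, 5), c(-20, 30)),
              unstable = list(c(-15, 10), c(10, -25),
                              c(fix_pattern$kJ1, fix_pattern$kJ2)))
  mesh <- build_icosphere(2)
  for (kind in names(pts)) {
    for (p in pts[[kind]]) {
      # mask verdict from the spectral module
      ctx <- lumped_context(p[1], p[2], fix_pattern$sigma1, fix_pattern$sigma2,
                            dl, n_max = 5)
      ev <- rightmost_eigenvalue(ctx, grid = 12)
      expect_identical(Re(ev$lam) < 0, kind == "stable")
      cal <- calibrate_couplings(p[1], p[2], fir,
                                 c(fix_pattern$sigma1, fix_pattern$sigma2), dl)
      cfg <- sim_config(dt = 0.05, t_end = 150, level = 2, save_every = 60,
                        n_max = 5, history = history_random(cal$equilibrium$u_hat, 1e-3),
                        seed = 99)
      tr <- simulate_field(cal$params, cfg, mesh = mesh)
      a0 <- 1e-3
      aT <- max(abs(tr$field_final - cal$equilibrium$u_hat))
      if (kind == "stable") expect_lt(aT / a0, 0.5) else expect_gt(aT / a0, 2)
    }
  }
})

test_that("halving the step changes the trajectory by less than one percent", {
  cal <- calibrate_couplings(fix_pattern$kJ1, fix_pattern$kJ2, fix_pattern$firing,
                             c(fix_pattern$sigma1, fix_pattern$sigma2),
                             fix_pattern$delay)
  mesh <- build_icosphere(3)
  cp <- delayed_coupling(mesh, cal$params)
  run <- function(dt) {
    cfg <- sim_config(dt = dt, t_end = 20, level = 3, save_every = round(2 / dt),
                      n_max = 4, history = history_random(cal$equilibrium$u_hat, 1e-2),
                      seed = 5)
    simulate_field(cal$params, cfg, mesh = mesh, coupling = cp)
  }
  tra <- run(0.1)
  trb <- run(0.05)
  scale <- max(abs(tra$field_final - cal$equilibrium$u_hat))
  expect_lt(max(abs(tra$field_final - trb$field_final)) / scale, 0.01)
})

test_that("mesh refinement leaves the leading-mode growth rate nearly unchanged", {
  cal <- calibrate_couplings(fix_pattern$kJ1, fix_pattern$kJ2, fix_pattern$firing,
                             c(fix_pattern$sigma1, fix_pattern$sigma2),
                             fix_pattern$delay)
  ctx <- lumped_context(fix_pattern$kJ1, fix_pattern$kJ2, fix_pattern$sigma1,
                        fix_pattern$sigma2, fix_pattern$delay, n_max = 4)
  lam_cont <- solve_modes(ctx, 4, list(re = c(-1, 1), im = c(0, 3)))$lam[1]
  lams <- lapply(3:4, function(lev) {
    cp <- delayed_coupling(build_icosphere(lev), cal$params)
    discrete_mode_eigenvalue(cp, 4, cal$equilibrium$kappa, lam_cont)
  })
  # levels 3 and 4 agree on the oscillation frequency to a fraction of a
  # percent and bracket the continuum growth rate tightly
  expect_lt(abs(Im(lams[[1]]) / Im(lams[[2]]) - 1), 0.02)
  expect_lt(abs(Re(lams[[1]]) - Re(lams[[2]])), 0.02 * abs(Im(lam_cont)))
  expect_lt(Mod(lams[[2]] - lam_cont), 0.01)
})

test_that("runaway states trip the guard and return the last finite state", {
  conn <- connectivity_params(1, -0.5, 1, 0.5)
  pars <- model_params(firing_params(1, 4, 0), conn, delay_params(1, 1))
  cfg <- sim_config(dt = 0.05, t_end = 10, level = 0, save_every = 10,
                    n_max = 1, history = history_constant(1e7))
  expect_warning(tr <- simulate_field(pars, cfg), "last finite")
  expect_false(tr$completed)
  expect_true(all(is.finite(tr$field_final)))
})
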