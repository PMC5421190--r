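test_that("kernel coefficients obey no-delay, zero-argument and conjugate limits", {
  # tau == 0 (c large, tau0 = 0): G_n independent of lambda
  ctx0 <- lumped_context(2, -3, 1, 0.5, delay_params(0, 1e9), n_max = 3)
  g_a <- G_n(ctx0, 2, 0.3 + 0.4i)
  g_b <- G_n(ctx0, 2, -1.5 + 2i)
  expect_lt(Mod(g_a - g_b), 1e-8)
  # lambda = 0 gives the pure kernel coefficient; degree 0 equals the mass
  ctx <- lumped_context(1.678, -4.367, 1, 0.5, delay_params(3, 1), n_max = 4)
  conn <- connectivity_params(1.678, -4.367, 1, 0.5)
  expect_equal(Re(G_n(ctx, 0, 0)), total_kernel_mass(conn), tolerance = 1e-9)
  wn <- funk_hecke(function(s) kernel_profile(s, conn), 3)
  expect_equal(G_n(ctx, 3, 0), wn + 0i, tolerance = 1e-9)
  # conjugate symmetry
  set.seed(2)
  for (k in 1:4) {
    lam <- complex(real = rnorm(1), imaginary = rnorm(1))
    expect_equal(G_n(ctx, k - 1, Conj(lam)), Conj(G_n(ctx, k - 1, lam)),
                 tolerance = 1e-12)
  }
})

test_that("G_n_prime matches finite differences and constant-delay factorization", {
  ctx <- lumped_context(1.678, -4.367, 1, 0.5, delay_params(3, 1), n_max = 3)
  set.seed(3)
  for (k in 1:4) {
    lam <- complex(real = runif(1, -2, 1), imaginary = runif(1, 0, 3))
    h <- 1e-6
    fd <- (G_n(ctx, 1, lam + h) - G_n(ctx, 1, lam - h)) / (2 * h)
    expect_lt(Mod(fd - G_n_prime(ctx, 1, lam)) / Mod(fd), 1e-6)
  }
  # constant delay: derivative factor pulls out as -tau0
  ctxc <- lumped_context(2, -1, 1, 0.5, delay_params(2.5, 1e9), n_max = 2)
  lam <- 0.2 + 0.7i
  expect_equal(G_n_prime(ctxc, 1, lam), -2.5 * G_n(ctxc, 1, lam),
               tolerance = 1e-7)
  # real lambda gives real derivative
  expect_lt(abs(Im(G_n_prime(ctx, 2, 0.4 + 0i))), 1e-12)
})

test_that("characteristic equation has explicit roots without delay and for kappa 0", {
  # no delay: all eigenvalues real, lambda_n = -1 + kappa * w_n
  conn <- connectivity_params(3, -2, 1 / 3, 1 / 4)
  dl <- delay_params(0, 1e9)
  ctx <- lumped_context(3, -2, 1 / 3, 1 / 4, dl, n_max = 4)
  for (n in 0:4) {
    wn <- Re(funk_hecke(function(s) kernel_profile(s, conn), n))
    ev <- solve_modes(ctx, n, list(re = c(-6, 2), im = c(0, 4)))
    expect_identical(nrow(ev), 1L)
    expect_equal(Re(ev$lam), -1 + wn, tolerance = 1e-8)
    expect_equal(Im(ev$lam), 0)
    expect_lt(Mod(E_n(ctx, n, -1 + wn)), 1e-9)
  }
  # kappa = 0: unique root at -1 for every degree
  ctx0 <- lumped_context(0, 0, 1, 0.5, delay_params(3, 1), n_max = 3)
  for (n in 0:3) {
    ev <- solve_modes(ctx0, n)
    expect_identical(nrow(ev), 1L)
    expect_equal(ev$lam, -1 + 0i, tolerance = 1e-10)
  }
  ev <- rightmost_eigenvalue(ctx0)
  expect_equal(ev$lam, -1 + 0i, tolerance = 1e-10)
})

test_that("pattern regime puts the only unstable pair at degree 4", {
  ctx <- lumped_context(fix_pattern$kJ1, fix_pattern$kJ2, fix_pattern$sigma1,
                        fix_pattern$sigma2, fix_pattern$delay, n_max = 5)
  box <- list(re = c(-6, 1), im = c(-8, 8))
  sp <- compute_spectrum(ctx, box)
  pos <- sp[Re(sp$lam) > 0, ]
  expect_identical(sort(unique(pos$n)), 4L)
  expect_identical(nrow(pos), 2L)  # a conjugate pair
  expect_true(all(sp$residual <= 1e-9))
  # spectrum is closed under conjugation
  for (i in seq_len(nrow(sp))) {
    d <- Mod(sp$lam - Conj(sp$lam[i]))
    expect_lt(min(d[sp$n == sp$n[i]]), 1e-6)
  }
  rm <- rightmost_eigenvalue(ctx)
  expect_identical(rm$n, 4L)
  expect_gt(Re(rm$lam), 0)
})

test_that("root counts agree with the argument-principle winding number", {
  ctx <- lumped_context(fix_pattern$kJ1, fix_pattern$kJ2, fix_pattern$sigma1,
                        fix_pattern$sigma2, fix_pattern$delay, n_max = 5)
  box <- list(re = c(-5.5, 1.3), im = c(-7.7, 7.7))
  for (n in c(0L, 4L)) {
    ev <- solve_modes(ctx, n, box, grid = 40L)
    expect_identical(winding_count(ctx, n, box), nrow(ev))
    expect_identical(nrow(solve_modes(ctx, n, box, verify = TRUE)), nrow(ev))
  }
})

test_that("kernel coefficients decay with degree, supporting the truncation", {
  ctx <- lumped_context(2, -3, 1, 0.5, delay_params(3, 1), n_max = 20)
  g <- vapply(c(2, 5, 10, 20), function(n) Mod(G_n(ctx, n, 0)), numeric(1))
  expect_true(all(diff(g) < 0))
  expect_lt(g[4] / g[1], 1e-2)
})

test_that("resolvent inverts the characteristic operator degree-wise", {
  ctx <- lumped_context(1.678, -4.367, 1, 0.5, delay_params(3, 1), n_max = 4)
  mesh <- build_icosphere(3)
  set.seed(4)
  y_field <- rnorm(nrow(mesh$vertices), sd = 0.3)
  y <- project_degrees(y_field, mesh, 4)
  mu <- 0.3 + 0.9i
  q <- resolvent_coefficients(y, mu, ctx)
  # forward operator: multiply degree-wise by E_n(mu) recovers y
  back <- q$coefficients
  for (n in 0:4) {
    idx <- spherefield:::nm_index(n, -n:n)
    back[idx] <- back[idx] * E_n(ctx, n, mu)
  }
  expect_lt(max(Mod(back - y$coefficients)), 1e-8)
  # trivial cases
  y0 <- project_degrees(rep(0, nrow(mesh$vertices)), mesh, 4)
  expect_equal(max(Mod(resolvent_coefficients(y0, mu, ctx)$coefficients)), 0)
  ctx0 <- lumped_context(0, 0, 1, 0.5, delay_params(3, 1), n_max = 4)
  q0 <- resolvent_coefficients(y, mu, ctx0)
  expect_equal(q0$coefficients, y$coefficients / (mu + 1), tolerance = 1e-12)
  # near-singular mu rejected: use an actual eigenvalue
  ev <- solve_modes(ctx, 0, default_box(ctx))
  expect_error(resolvent_coefficients(y, ev$lam[1], ctx), "point spectrum")
})

test_that("Q_n matches the resolvent applied to a constant field", {
  ctx <- lumped_context(1.565, -4.075, 1, 0.5, delay_params(3, 1), n_max = 2)
  expect_equal(Q_n(ctx, 1, 0.5), G_n(ctx, 1, 0.5) / (1.5 - G_n(ctx, 1, 0.5)),
               tolerance = 1e-12)
  ctx0 <- lumped_context(0, 0, 1, 0.5, delay_params(3, 1), n_max = 2)
  mu <- 0.2 + 0.1i
  expect_equal(Q_n(ctx0, 1, mu), G_n(ctx0, 1, mu) / (mu + 1), tolerance = 1e-12)
  # constant field: resolvent coefficient at degree 0 equals (1 + kappa Q_0) y00
  mesh <- build_icosphere(2)
  y <- project_degrees(rep(1, nrow(mesh$vertices)), mesh, 0)
  q <- resolvent_coefficients(y, 0, ctx)
  # q00 = y00 / E_0(0) and Q_0(0) = G_0(0)/E_0(0): consistent identity
  expect_equal(q$coefficients[1] * (1 - G_n(ctx, 0, 0)), y$coefficients[1],
               tolerance = 1e-10)
})

test_that("contexts validate equilibria and record branch selection", {
  conn <- connectivity_params(1.7, -4.4, 1, 0.5)
  pars <- model_params(firing_params(1, 4, 0.1), conn, delay_params(3, 1))
  ctx <- linearization_context(pars, n_max = 2)
  expect_lt(ctx$equilibrium$residual, 1e-10)
  bad_eq <- structure(list(u_hat = 0.5, kappa = 1, w0 = 0, residual = 1),
                      class = "equilibrium")
  expect_error(linearization_context(pars, bad_eq), "residual")
})
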