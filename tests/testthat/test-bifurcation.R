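test_that("fold lines carry a zero-eigenvalue certificate", {
  dl <- fix_nodelay$delay
  fl <- fold_line(2, fix_nodelay$sigma1, fix_nodelay$sigma2, dl)
  # sample points on the line a*kJ1 + b*kJ2 = 1 and verify E_2(0) = 0
  for (kJ1 in c(-3, 0, 2)) {
    kJ2 <- (1 - fl$a * kJ1) / fl$b
    ctx <- lumped_context(kJ1, kJ2, fix_nodelay$sigma1, fix_nodelay$sigma2,
                          dl, n_max = 2)
    expect_lt(Mod(E_n(ctx, 2, 0)), 1e-9)
  }
  # axis intercept of the degree-0 line
  fl0 <- fold_line(0, fix_nodelay$sigma1, fix_nodelay$sigma2, dl)
  ctx <- lumped_context(1 / fl0$a, 0, fix_nodelay$sigma1, fix_nodelay$sigma2,
                        dl, n_max = 0)
  expect_lt(Mod(E_n(ctx, 0, 0)), 1e-9)
  # slope matches finite-difference continuation of the lambda = 0 root:
  # moving along the line keeps the root at 0
  kJ1s <- c(0.5, 0.6)
  roots <- vapply(kJ1s, function(kJ1) {
    kJ2 <- (1 - fl$a * kJ1) / fl$b
    ctx <- lumped_context(kJ1, kJ2, fix_nodelay$sigma1, fix_nodelay$sigma2,
                          dl, n_max = 2)
    ev <- solve_modes(ctx, 2, list(re = c(-0.5, 0.5), im = c(0, 0.5)))
    min(Mod(ev$lam))
  }, numeric(1))
  expect_true(all(roots < 1e-8))
})

test_that("Hopf curves certify their points and meet the fold line as omega -> 0", {
  dl <- fix_hopf$delay
  hc <- hopf_curve(0, seq(0.2, 1.4, by = 0.2), fix_hopf$sigma1, fix_hopf$sigma2, dl)
  expect_true(all(hc$residual <= 1e-9))
  for (i in seq_len(nrow(hc))) {
    ctx <- lumped_context(hc$kJ1[i], hc$kJ2[i], fix_hopf$sigma1,
                          fix_hopf$sigma2, dl, n_max = 0)
    expect_lt(Mod(E_n(ctx, 0, 1i * hc$omega[i])), 1e-9)
  }
  # omega -> 0 limit approaches the fold line
  small <- hopf_curve(0, 1e-4, fix_hopf$sigma1, fix_hopf$sigma2, dl)
  fl <- fold_line(0, fix_hopf$sigma1, fix_hopf$sigma2, dl)
  expect_lt(abs(fl$a * small$kJ1 + fl$b * small$kJ2 - 1), 1e-3)
})

test_that("the balanced degree-0 Hopf point sits at the reported gains and frequency", {
  hp <- balanced_hopf_point(0, fix_hopf$sigma1, fix_hopf$sigma2, fix_hopf$delay)
  expect_rel_equal(hp$omega, 0.950, 0.02)
  expect_rel_equal(hp$kJ1, 1.565, 0.02)
  expect_rel_equal(hp$kJ2, -4.075, 0.02)
  expect_lt(hp$residual, 1e-9)
  # the point is balanced: kernel mass vanishes for the implied couplings
  a0 <- Re(hn_coefficient(0, 0, fix_hopf$sigma1, fix_hopf$delay))
  b0 <- Re(hn_coefficient(0, 0, fix_hopf$sigma2, fix_hopf$delay))
  expect_lt(abs(a0 * hp$kJ1 + b0 * hp$kJ2), 1e-9)
})

test_that("stability mask is stable at the origin and unstable at the pattern point", {
  dl <- fix_pattern$delay
  mask <- stability_mask(c(-5, 0, fix_pattern$kJ1), c(-20, 0, fix_pattern$kJ2),
                         fix_pattern$sigma1, fix_pattern$sigma2, dl, n_max = 5)
  origin <- mask[mask$kJ1 == 0 & mask$kJ2 == 0, ]
  expect_true(origin$stable)
  expect_equal(origin$max_re, -1, tolerance = 1e-8)
  corner <- mask[mask$kJ1 == fix_pattern$kJ1 & mask$kJ2 == fix_pattern$kJ2, ]
  expect_false(corner$stable)
})

test_that("bifurcation curves bound the stability mask (overlay agreement)", {
  # no-offset-delay regime: every stable/unstable cell transition of a
  # coarse mask must have a fold line or Hopf curve passing nearby
  dl <- fix_nodelay$delay
  s1 <- fix_nodelay$sigma1; s2 <- fix_nodelay$sigma2
  kj1 <- seq(-6, 6, length.out = 7)
  kj2 <- seq(-8, 8, length.out = 7)
  mask <- stability_mask(kj1, kj2, s1, s2, dl, n_max = 5)
  curve_pts <- do.call(rbind, lapply(0:5, function(n) {
    hc <- hopf_curve(n, seq(0.05, 6, length.out = 120), s1, s2, dl)
    fl <- fold_line(n, s1, s2, dl)
    kline <- seq(min(kj1) - 2, max(kj1) + 2, length.out = 200)
    rbind(hc[, c("kJ1", "kJ2")],
          data.frame(kJ1 = kline, kJ2 = (1 - fl$a * kline) / fl$b))
  }))
  h1 <- diff(kj1)[1]; h2 <- diff(kj2)[1]
  get_cell <- function(i, j) mask[mask$kJ1 == kj1[i] & mask$kJ2 == kj2[j], ]
  n_edges <- 0L
  for (i in seq_along(kj1)) for (j in seq_along(kj2)) {
    a <- get_cell(i, j)
    if (is.na(a$stable)) next
    for (d in list(c(1, 0), c(0, 1))) {
      i2 <- i + d[1]; j2 <- j + d[2]
      if (i2 > length(kj1) || j2 > length(kj2)) next
      b <- get_cell(i2, j2)
      if (is.na(b$stable) || a$stable == b$stable) next
      n_edges <- n_edges + 1L
      # some bifurcation curve must pass within one cell of the edge
      mid <- c((a$kJ1 + b$kJ1) / 2, (a$kJ2 + b$kJ2) / 2)
      near <- abs(curve_pts$kJ1 - mid[1]) <= h1 & abs(curve_pts$kJ2 - mid[2]) <= h2
      expect_true(any(near),
                  info = sprintf("no curve near transition at (%g, %g)",
                                 mid[1], mid[2]))
    }
  }
  expect_gt(n_edges, 0L)  # the grid does straddle the boundary
})

test_that("first Lyapunov coefficient: degenerate limits, signs and invariance", {
  # vanishing curvature: g21 = 0 when f'' and f''' vanish
  expect_equal(normal_form_g21(0.95, 1, 0.3 + 0.2i, 0.1 + 0.4i, -0.2, 0, 0),
               0 + 0i)
  hp <- balanced_hopf_point(0, fix_hopf$sigma1, fix_hopf$sigma2, fix_hopf$delay)
  nf40 <- lyapunov_coefficient(hp, firing_params(1, 4, 0.40))
  nf48 <- lyapunov_coefficient(hp, firing_params(1, 4, 0.48))
  expect_lt(nf40$l1, 0)
  expect_identical(nf40$criticality, "supercritical")
  expect_gt(nf48$l1, 0)
  expect_identical(nf48$criticality, "subcritical")
  expect_equal(nf40$l1, Re(nf40$g21) / nf40$omega0)
  # l1 depends only on lumped gains and equilibrium derivatives: rescaling
  # (J1, J2, kappa) -> (aJ, kappa/a) leaves the diagnostics' lumped parts
  # unchanged, so l1 computed from the same hopf_point and firing is the
  # canonical value; check invariance under quadrature refinement instead
  hp2 <- hopf_point(0, hp$omega, fix_hopf$sigma1, fix_hopf$sigma2, fix_hopf$delay)
  nf40b <- lyapunov_coefficient(hp2, firing_params(1, 4, 0.40))
  expect_equal(nf40b$l1, nf40$l1, tolerance = 1e-10)
  # degree > 0 points are rejected (simple-pair formula)
  hp1 <- tryCatch(balanced_hopf_point(1, fix_hopf$sigma1, fix_hopf$sigma2,
                                      fix_hopf$delay),
                  error = function(e) NULL)
  if (!is.null(hp1)) expect_error(lyapunov_coefficient(hp1, firing_params(1, 4, 0.4)),
                                  "degree-0")
})

test_that("generalized Hopf point is located at the reported threshold", {
  gh <- find_generalized_hopf(1, 4, c(0.40, 0.48), fix_hopf$sigma1,
                              fix_hopf$sigma2, fix_hopf$delay)
  expect_rel_equal(gh$delta_star, 0.4172, 0.02)
  expect_rel_equal(gh$omega0, 0.950, 0.02)
  expect_lt(gh$certificates["l1"], 1e-8)
  # opposite signs just below/above the located threshold
  hp <- gh$hopf_point
  below <- lyapunov_coefficient(hp, firing_params(1, 4, gh$delta_star - 1e-3))$l1
  above <- lyapunov_coefficient(hp, firing_params(1, 4, gh$delta_star + 1e-3))$l1
  expect_lt(below, 0)
  expect_gt(above, 0)
  expect_error(find_generalized_hopf(1, 4, c(0.46, 0.48), fix_hopf$sigma1,
                                     fix_hopf$sigma2, fix_hopf$delay),
               "sign")
})

test_that("double-Hopf solver reproduces the codim-2 point with certificates", {
  dh <- find_double_hopf(firing_params(1, 4, 0.1), fix_hopf$sigma1,
                         fix_hopf$sigma2, c = 1, tau0_init = 3)
  expect_rel_equal(dh$omega0, 0.861, 0.05)
  expect_rel_equal(dh$omega1, 0.609, 0.05)
  expect_rel_equal(dh$tau0, 3.483, 0.05)
  expect_rel_equal(dh$J1, 1.678, 0.05)
  expect_rel_equal(dh$J2, -4.367, 0.05)
  expect_true(all(dh$certificates <= 1e-8))
  expect_gt(dh$nonresonance_margin, 1e-3)
  # both critical pairs sit on the imaginary axis of the full spectrum
  ctx <- linearization_context(dh$params, n_max = 1)
  ev0 <- solve_modes(ctx, 0, list(re = c(-1, 1), im = c(0, 3)))
  ev1 <- solve_modes(ctx, 1, list(re = c(-1, 1), im = c(0, 3)))
  expect_lt(min(abs(Re(ev0$lam))), 1e-7)
  expect_lt(min(abs(Re(ev1$lam))), 1e-7)
  # no third mode is critical: degrees 2..4 stay strictly in the left plane
  ctx4 <- linearization_context(dh$params, n_max = 4)
  for (n in 2:4) {
    ev <- solve_modes(ctx4, n, list(re = c(-1, 1), im = c(0, 3)))
    if (nrow(ev)) expect_lt(max(Re(ev$lam)), -1e-3)
  }
})
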