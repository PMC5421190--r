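# Shared fixtures: the parameter regimes used throughout the suite.

# Pattern-forming regime with non-zero offset delay (narrow kernels); the
# homogeneous state has lost stability to a degree-4 Hopf mode.
fix_pattern <- list(kJ1 = 29.50, kJ2 = -51.38, sigma1 = 2 / 9, sigma2 = 1 / 6,
                    delay = delay_params(3, 0.8),
                    firing = firing_params(1, 8, 0))

# Balanced-kernel Hopf regime used for the normal-form continuation.
fix_hopf <- list(sigma1 = 1, sigma2 = 1 / 2, delay = delay_params(3, 1),
                 alpha = 1, beta = 4)

# No-offset-delay regime (fold/Hopf structure dominated by low degrees).
fix_nodelay <- list(sigma1 = 1 / 3, sigma2 = 1 / 4, delay = delay_params(0, 0.8))

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}

# Brute-force double surface integral of g(r . r') against the zonal
# harmonic Y_n^0 on both spheres. The outer azimuth integrates out by
# rotational symmetry, leaving a (theta, theta', phi') tensor quadrature;
# the resolution below keeps the cusp of the kernel at zero separation
# resolved to ~1e-7 relative.
double_surface_oracle <- function(g, n, N = c(96L, 256L, 768L)) {
  glo <- pracma::gaussLegendre(N[1], 0, pi)
  gli <- pracma::gaussLegendre(N[2], 0, pi)
  phv <- seq(0, 2 * pi, length.out = N[3] + 1L)[-(N[3] + 1L)]
  yfun <- function(th) {
    Re(spherical_harmonic(n, 0, th, rep(0, length(th))))
  }
  yo <- yfun(glo$x)
  yi <- gli$w * sin(gli$x) * yfun(gli$x)
  acc <- 0 + 0i
  for (i in seq_len(N[1])) {
    th <- glo$x[i]
    cg <- outer(cos(th) * cos(gli$x), rep(1, N[3])) +
      outer(sin(th) * sin(gli$x), cos(phv))
    cg[cg > 1] <- 1
    cg[cg < -1] <- -1
    inner <- sum(yi * rowSums(g(cg))) * (2 * pi / N[3])
    acc <- acc + glo$w[i] * sin(th) * yo[i] * inner
  }
  2 * pi * acc
}
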