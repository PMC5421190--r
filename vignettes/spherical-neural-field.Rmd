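---
title: "Delayed neural field dynamics on the sphere: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed neural field dynamics on the sphere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spherefield)
```

## The model

`spherefield` analyses and simulates a voltage-based neural field of Nunez
type posed on the unit sphere $\Omega = S^2$, a minimal geometry for
whole-cortex EEG modelling:

$$\frac{\partial u(t,r)}{\partial t} = -u(t,r)
  + \int_\Omega w(r \cdot r')\, f\!\big(u(t - \tau(r\cdot r'), r')\big)\, dr'.$$

Here $u$ is the synaptic activity at a point $r$ on the sphere, $f$ a
sigmoidal firing rate, $w$ a rotation-invariant synaptic kernel and $\tau$ a
distance-dependent axonal delay. The concrete constitutive choices are

* firing rate $f(u) = \alpha / (1 + e^{-\beta(u - \delta)})$ with maximal
  rate $\alpha > 0$ (dimensionless activity per unit time after rescaling),
  steepness $\beta > 0$ and threshold $\delta$;
* kernel $w(s) = J_1 e^{-\arccos(s)/\sigma_1} + J_2 e^{-\arccos(s)/\sigma_2}$,
  a sum of two exponentials in the great-circle distance with angular scales
  $\sigma_1 > \sigma_2 > 0$ (radians) and amplitudes of opposite sign
  ("wizard hat" when $J_1 + J_2 > 0$);
* delay $\tau(s) = \tau_0 + \arccos(s)/c$ with offset delay $\tau_0 \ge 0$
  (synaptic/relaxation time scale) and finite propagation speed $c > 0$
  (radians per time unit). The maximal delay is $h = \tau_0 + \pi/c$.

Because both $w$ and $\tau$ depend only on $r \cdot r'$, the linearization
about a homogeneous state diagonalizes in spherical harmonics: by the
Funk–Hecke theorem the delayed kernel acts on degree-$n$ harmonics with the
scalar gain

$$G_n(\lambda) = 2\pi \int_{-1}^{1} w(s)\, e^{-\lambda \tau(s)} P_n(s)\, ds
  = J_1 h_n(\lambda;\sigma_1) + J_2 h_n(\lambda;\sigma_2),$$

and the point spectrum consists of the roots of the characteristic equations
$E_n(\lambda) = \lambda + 1 - \kappa G_n(\lambda)$, $\kappa = f'(\hat u)$,
each of multiplicity $2n+1$; the essential spectrum is the single point
$-1$. Everything else in the package — bifurcation curves, normal-form
coefficients, codimension-2 continuation, planforms, and the mesh simulator
— is built on this decomposition.

## Parameters that matter

| parameter | meaning | typical values used here |
|---|---|---|
| $\alpha, \beta, \delta$ | firing ceiling, gain, threshold | $\alpha = 1$, $\beta \in \{4, 8\}$, $\delta \in [0, 0.5]$ |
| $J_1, J_2$ | kernel amplitudes (excitation/inhibition) | $O(1)$–$O(10)$, opposite signs |
| $\sigma_1, \sigma_2$ | kernel angular scales (rad) | $(1, 1/2)$ broad; $(2/9, 1/6)$ narrow |
| $\tau_0$ | offset delay (time units) | $0$–$3.5$ |
| $c$ | propagation speed (rad/time) | $0.8$–$1$ |

Stability diagrams are drawn in the *lumped gains* $(\kappa J_1, \kappa J_2)$
because the linear problem depends on the couplings only through these
products. The catch is that $\kappa = f'(\hat u)$ itself depends on
$(J_1, J_2)$ through the equilibrium condition $\hat u = w_0 f(\hat u)$,
where $w_0 = G_0(0)$ is the kernel mass. `calibrate_couplings()` resolves
this circularity: it reduces the three-equation system
$\{\kappa J_i = t_i,\ \hat u = w_0 f(\hat u)\}$ to a scalar root-find in
$\hat u$ and returns raw amplitudes realizing requested lumped gains.
Not every lumped pair is realizable at a given firing rate: $\kappa$ is
bounded by $\alpha\beta/4$, and the equilibrium moves with the couplings —
the calibration reports failure rather than inventing a branch. When several
equilibria coexist, the branch whose leading degree-0 eigenvalue pair is
closest to the imaginary axis is selected (the one undergoing the
bifurcations of interest); this is a package convention, recorded in the
context's `branch_note`, since the destabilizing branch is the one whose
instabilities the analysis tracks.

### The balanced-kernel convention

A kernel with $w_0 = 0$ is *balanced*: $\hat u = 0$ is then the unique
homogeneous equilibrium and $\kappa = f'(0)$ is explicit. The normal-form
continuations anchor their Hopf points on the balanced line for exactly this
reason: `balanced_hopf_point()` intersects the degree-0 Hopf curve with the
balanced line in the lumped plane, and the generalized-Hopf continuation in
the threshold $\delta$ (`find_generalized_hopf()`) holds that point fixed
while $\kappa(\delta)$, $f''(0)$ and $f'''(0)$ vary. The Hopf curve/balanced
line intersection closest to the origin on the $\kappa J_1 > 0$ side is used
— it is the one bounding the stability region on that side. The double-Hopf
solver (`find_double_hopf()`) closes its five-unknown system
$(J_1, J_2, \tau_0, \omega_0, \omega_1)$ with the same balance constraint:
the equilibrium equation is then satisfied identically by $\hat u = 0$, and
the offset delay $\tau_0$ is the unfolding parameter that brings the
degree-0 and degree-1 Hopf curves to a common point.

## Numerical choices

**Quadrature.** All Funk–Hecke transforms substitute $s = \cos\theta$: the
kernels are smooth in the angle $\theta$ (they are *not* smooth in $s$ at
$s = 1$, where $\arccos$ has a square-root branch), so Gauss–Legendre in
$\theta$ converges spectrally. `funk_hecke()` doubles the order until two
consecutive orders agree to $10^{-10}$ relative (cap $2^{14}$); the
spectral contexts freeze a converged rule at construction so that root
finding reduces to dot products.

**Root finding.** `solve_modes()` runs vectorized Newton iterations from a
uniform seed grid (default $25 \times 25$) over the search box, deduplicates,
completes conjugates, then polishes on a doubled-order rule. The residual
certificate stored with each eigenvalue is $|E_n(\lambda)|$ scaled by the
magnitude of its own evaluation (a backward-error measure): near the
imaginary axis — where every scientific claim lives — the scale is one and
this is the plain absolute residual; deep in the left half-plane the
evaluation involves terms of size $e^{|\mathrm{Re}\,\lambda| h}$ and no
absolute bound is meaningful in double precision. The default box
$\mathrm{Re} \in [-6, 2]$, $\mathrm{Im} \in [0, 2\pi/h + 10]$ covers the
rightmost delay-induced branches; an argument-principle winding count on
the box boundary (`winding_count()`, `verify = TRUE`) guards against missed
roots.

**First Lyapunov coefficient.** The cubic coefficient of the degree-0 Hopf
normal form is evaluated as
$$g_{21} = \frac{1 + i\omega_0}{8\pi\kappa\,(1 - \kappa G_0'(i\omega_0))}
  \Big(f'''(\hat u) + f''(\hat u)^2 \big[Q_0(2i\omega_0) + 2 Q_0(0)\big]\Big),
  \qquad Q_n(\mu) = \frac{G_n(\mu)}{\mu + 1 - \kappa G_n(\mu)},$$
with $l_1 = \mathrm{Re}(g_{21})/\omega_0$ deciding criticality (negative =
supercritical). Two remarks on this expression as implemented. First, the
derivative $G_0'$ is evaluated at the critical eigenvalue $i\omega_0$ (the
only argument for which the expression is meaningful; the diagnostics field
records this). Second, the placement of $\kappa$ in the prefactor only
rescales $g_{21}$ by the positive factor $\kappa^2$ relative to the
alternative reading, so the sign of $l_1$, the location of its zero in
$\delta$, and every criticality conclusion are insensitive to it. The
implementation is cross-validated by two mandatory tests: the sign of $l_1$
on both sides of the generalized Hopf point, and the threshold location
$\delta^* \approx 0.4172$ itself.

**Amplitude equations.** The degree-0/degree-1 double-Hopf normal form is
implemented with its cubic coefficients as *inputs*: every qualitative
statement about the reduced dynamics (equilibrium count, bistability of the
pure modes) depends only on the unfolding parameters and the real parts of
the cubic coefficients, which `sample_dhopf_coefficients()` draws at random
(log-normal magnitudes, all real parts negative — the dissipative regime).
The `all_six` regime additionally imposes the cross-coupling-dominance
inequalities under which all six first-octant equilibria of the reduced
system coexist; in that regime exactly the two pure-mode points (bulk
oscillation, travelling wave) are linearly stable, the package's
multistability statement. The closed-form equilibrium enumeration is
cross-checked in the tests against a damped-Newton multistart search whose
starts cycle through all coordinate-plane masks (Newton preserves the
planes $\{x_i = 0\}$, so boundary equilibria are reachable only from within
their plane) with squared-uniform radii to cover small-coordinate roots.

**Planform fix vectors.** The degree-4 catalog stores the octahedral and
tetrahedral fixed-point vectors with the square-root ratios
$(\sqrt5, \sqrt{14}, \sqrt5)$ and
$(\sqrt7, \sqrt{12}i, -\sqrt{10}, \sqrt{12}i, \sqrt7)$: these are the
ratios for which the combinations of degree-4 harmonics are invariant under
the three-fold axes of the octahedral/tetrahedral groups (the familiar
cubic harmonic $Y_4^0 + \sqrt{5/14}\,(Y_4^4 + Y_4^{-4})$ in the octahedral
case). The test suite demonstrates that the plain integer vectors
$(5, 14, 5)$ and $(7, 12i, -10, 12i, 7)$ — a plausible alternative reading
of typeset tables that drop radical signs — fail the three-fold-axis
symmetry residual by $10^{-1}$ while the radical vectors pass at machine
precision, so the choice is verified, not assumed.

**Simulator.** `simulate_field()` advances the field with Heun (explicit
trapezoidal) steps; the delayed integral uses dense precomputed matrices
$W_{ij} = w(r_i\cdot r_j)\,w_j$ and $\tau_{ij}$, a ring buffer of
firing-rate snapshots at step resolution, and linear interpolation in time
(lag indices are constant, so each right-hand side is two gathers and a row
sum). Two discretization choices deserve emphasis:

* *Row-sum correction.* The kernel's cusp at zero separation makes plain
  vertex-area quadrature inaccurate for narrow kernels (modal-gain errors
  of several percent at level 3 for $\sigma_2 = 1/6$). The self-coupling
  entry of each row is therefore adjusted so the row sum reproduces the
  exact kernel mass $w_0$ — a near-field product-integration correction
  that removes the leading quadrature error of every modal gain (to below
  1% at level 3) and makes homogeneous equilibria exact fixed points of
  the discretization.
* *Step-size guards.* $dt$ is capped at $h/10$ and, when $\tau_0 > 0$, at
  $\tau_0/2$, so every delayed lookup reaches fully computed history and
  the scheme stays explicit.

The discretization a given mesh level actually realizes can be probed
without time stepping via `discrete_mode_eigenvalue()`, the scalar
characteristic root of the Rayleigh-quotient modal gain; levels 3 and 4
agree to well under the continuum eigenvalue scale for the pattern-forming
regime, which is the package's mesh-refinement check.

## What the bundled experiments emulate — and what they do not

The synthetic experiments in the tests and in `scripts/acceptance.R` use the
regimes the analysis singles out: the narrow-kernel pattern regime
($\sigma = (2/9, 1/6)$, $\tau_0 = 3$, $c = 0.8$, $\beta = 8$, $\delta = 0$,
lumped gains $(29.50, -51.38)$) where the degree-4 pair is the unique
unstable mode; the balanced broad-kernel regime ($\sigma = (1, 1/2)$,
$\tau_0 = 3$, $c = 1$, $\beta = 4$) for the Hopf/generalized-Hopf/double-Hopf
continuations; and random perturbation fields for pattern selection. The
pattern-formation run uses a level-3 icosphere (642 vertices, 1280
triangles), time step $0.1$ and horizon $T = 300$ — chosen because the
unstable growth rate there is $\mathrm{Re}\,\lambda \approx 0.01$, so the
competing weakly damped degrees 3 and 5 need a few hundred time units to
fall behind in power; figure-quality runs use level 4 (5120 triangles).
Passing these tests shows the pipeline is internally consistent (spectral
predictions match direct simulation, symmetry certificates hold, the
reduced amplitude dynamics match the full normal form); it does not show
anything about real cortical geometry — a sphere has no folds, the kernel
is homogeneous and isotropic, delays are single-speed — nor about parameter
regimes far from the instabilities studied.

Degenerate and edge cases are handled explicitly rather than silently:
near-tangent equilibria are reported as fold candidates; Hopf-curve points
where the $2\times 2$ frequency system is ill-conditioned are skipped and
logged; resonances ($E_0$ singular at $0$ or $2i\omega_0$; $k\omega_0 =
l\omega_1$, $k + l \le 5$) abort the normal-form computations with errors;
stability-mask cells where the spectral solve fails are marked unknown,
never stable.

## Known limitations

* The Legendre series of the two-exponential kernel converges only like
  $O(N^{-1/2})$ *at* the cusp point $s = 1$ (the kernel is Lipschitz, not
  differentiable, there); partial-sum reconstruction to $10^{-3}$ holds on
  $[-1, 0.95]$ at $n_{\max} = 60$ but not at the apex itself.
* The scalar Lyapunov-coefficient machinery applies to the degree-0 Hopf
  bifurcation only (simple critical pair); degree-$n$ Hopf bifurcations
  with $n \ge 1$ get planform catalogs and simulation, not normal-form
  coefficients. The cubic coefficients of the double-Hopf normal form are
  accepted as inputs, not derived from the field model.
* The activity-based model variant (nonlinearity outside the integral),
  folded-cortex meshes, heterogeneous connectivity, distributed axonal
  speeds and stimulus forcing are out of scope.
* Quasi-periodic mixed-mode solutions of the reduced amplitude system are
  enumerated and classified but are unstable everywhere we sampled; no
  claim is made about their stability elsewhere.

## Reproducing the headline numbers

```{r}
# the pattern regime: the unique unstable pair has degree 4
ctx <- lumped_context(29.50, -51.38, 2/9, 1/6, delay_params(3, 0.8), n_max = 5)
spectrum_table(compute_spectrum(ctx, list(re = c(-6, 2), im = c(-8, 8))))

# balanced Hopf point and generalized Hopf threshold
balanced_hopf_point(0, 1, 1/2, delay_params(3, 1))
find_generalized_hopf(1, 4, c(0.40, 0.48), 1, 1/2, delay_params(3, 1))

# double-Hopf point with the offset delay as unfolding parameter
find_double_hopf(firing_params(1, 4, 0.1), 1, 1/2, c = 1, tau0_init = 3)
```

`scripts/acceptance.R` runs these computations end to end (plus the level-3
pattern-formation simulation and the amplitude-system survey) and writes the
resulting numbers to JSON; see the README for how to invoke it.
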