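# spherefield

Analysis and simulation of a delayed neural field of Nunez type on the unit
sphere — a minimal whole-cortex geometry for studying how EEG-scale
spatiotemporal patterns (bulk oscillations, standing and travelling waves,
rotating waves) emerge from the interplay of synaptic connectivity, axonal
conduction delays and firing-rate nonlinearity.

The model is the integro-differential equation

    du(t,r)/dt = -u(t,r) + ∫_Ω w(r·r') f(u(t - τ(r·r'), r')) dr',   r ∈ S²

with sigmoidal firing rate `f(u) = α/(1+exp(-β(u-δ)))`, two-exponential
kernel `w(s) = J₁ exp(-arccos(s)/σ₁) + J₂ exp(-arccos(s)/σ₂)` and
space-dependent delay `τ(s) = τ₀ + arccos(s)/c`. Because `w` and `τ` depend
only on `r·r'`, the linearization about a homogeneous state diagonalizes in
spherical harmonics (Funk–Hecke theorem): degree-`n` perturbations obey the
scalar transcendental characteristic equation

    E_n(λ) = λ + 1 - κ G_n(λ) = 0,
    G_n(λ) = 2π ∫₋₁¹ w(s) e^{-λτ(s)} P_n(s) ds,   κ = f'(û).

The package provides, for whom this matters (computational neuroscientists
and applied dynamicists working on delayed field models):

* **model core** — parameter containers, equilibria of `û = w₀ f(û)`, and
  calibration of raw couplings `(J₁, J₂)` to lumped gains `(κJ₁, κJ₂)`;
* **harmonics** — Legendre polynomials, orthonormal complex spherical
  harmonics, adaptive Funk–Hecke transforms, mesh-field degree projections;
* **spectral** — certified eigenvalue solvers for `E_n` (vectorized Newton
  plus argument-principle verification), resolvent coefficients;
* **bifurcation** — fold lines and parametric Hopf curves in the lumped-gain
  plane, stability masks, the first Lyapunov coefficient `l₁` of the
  degree-0 Hopf bifurcation, generalized-Hopf (Bautin) and double-Hopf
  codimension-2 point location;
* **amplitude** — the O(3)×S¹-equivariant cubic normal form for interacting
  degree-0/degree-1 Hopf modes, its exact reduction to a 3-D real ODE
  system, closed-form equilibrium enumeration, stability and isotropy-type
  classification;
* **planforms** — the catalog of C-axial symmetry branches for critical
  degrees 1–6 (with fixed-point vectors and generator sets at degree 4),
  planform synthesis and spatiotemporal-symmetry verification;
* **simulator** — direct integration of the delayed field on icosphere
  meshes (dense delay/kernel matrices, ring-buffer history, Heun stepping)
  with harmonic-power and center-of-mass diagnostics.

## Worked example

Locate the degree-0 Hopf point on the balanced-kernel line, follow the first
Lyapunov coefficient in the firing threshold, and find the nearby double-Hopf
point where the degree-1 modes become simultaneously critical:

```r
library(spherefield)
delay <- delay_params(tau0 = 3, c = 1)

balanced_hopf_point(0, sigma1 = 1, sigma2 = 1/2, delay)
#> Hopf point (degree n=0): omega=0.949623 kJ1=1.565384 kJ2=-4.074967 (|E_n(i omega)|=1.1e-16)

find_generalized_hopf(alpha = 1, beta = 4, c(0.40, 0.48), 1, 1/2, delay)
#> codimension-2 point: generalized_hopf
#>   delta* = 0.417235, omega0 = 0.949623, (kJ1, kJ2) = (1.5654, -4.0750)
#>   certificates: 1.11e-16 7.97e-09

find_double_hopf(firing_params(1, 4, 0.1), 1, 1/2, c = 1, tau0_init = 3)
#> codimension-2 point: double_hopf
#>   J1 = 1.6777, J2 = -4.3673, tau0 = 3.4826, omega0 = 0.8611, omega1 = 0.6091
#>   certificates: 8.88e-16 3.90e-12 2.47e-12 1.71e-12 7.74e-13
```

Reading: the oscillatory (Hopf) instability of the homogeneous state occurs
at lumped gains `(1.565, -4.075)` with angular frequency `ω₀ ≈ 0.950`; the
bifurcation switches from supercritical to subcritical (`l₁ = 0`,
bistability between rest and synchronous oscillation) at threshold
`δ* ≈ 0.4172`; and increasing the offset delay to `τ₀ ≈ 3.483` brings the
degree-1 travelling/standing-wave modes to criticality together with the
bulk mode (`ω₀ ≈ 0.861`, `ω₁ ≈ 0.609`) — the organizing center for
multistability between bulk oscillations and rotating waves. The
`certificates` entries are the characteristic-equation residuals of each
defining condition.

In a narrow-kernel regime the first instability is instead a patterned one;
the spectrum shows a single unstable conjugate pair of harmonic degree 4,

```r
ctx <- lumped_context(29.50, -51.38, 2/9, 1/6, delay_params(3, 0.8), n_max = 5)
subset(spectrum_table(compute_spectrum(ctx, list(re = c(-6, 2), im = c(-8, 8)))), re > 0)
#>   n         re        im     residual
#> 1 4 0.01024155  0.7552465 9.75e-15
#> 2 4 0.01024155 -0.7552465 9.75e-15
```

and a direct simulation from a small random perturbation develops a
degree-4 standing wave (see `run_simulate()` or the acceptance script).

## Command line

A thin wrapper over the `run_*()` functions lives at `inst/cli/spherefield`:

```sh
Rscript inst/cli/spherefield spectrum --config cfg.json --out results/
```

with subcommands `spectrum`, `stability-map`, `hopf-curves`, `normal-form`,
`codim2`, `amplitude`, `planform`, `simulate`. Configurations are flat JSON
(schema-validated; unknown keys are rejected) and every run writes a
manifest with the resolved configuration.
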