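Package: spherefield
Title: Delayed Neural Field Dynamics and Bifurcation Analysis on the Sphere
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing and simulating a delayed integro-differential
    neural field of Nunez type posed on the unit sphere. Provides the
    constitutive ingredients (sigmoidal firing rate, two-exponential
    connectivity kernel, distance-dependent axonal delays), spherical-harmonic
    spectral machinery built on the Funk-Hecke theorem, characteristic-equation
    eigenvalue solvers, fold and Hopf bifurcation curves in coupling-gain
    space, the first Lyapunov coefficient with generalized-Hopf and double-Hopf
    codimension-2 detection, the equivariant amplitude equations for the
    interacting degree-0 and degree-1 Hopf modes, a catalog of C-axial
    planforms with spatiotemporal symmetry verification, and a direct
    simulator of the full delayed field on triangulated icosphere meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
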