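Package: critwave
Title: Wave Propagation and Attenuation in Critically Balanced Cortical Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a critically balanced
    excitatory-inhibitory lattice model of cortex. Neurons sit on a
    checkerboard lattice and interact with their four nearest neighbours
    through an antisymmetric coupling matrix, so the linearised dynamics
    has purely imaginary eigenvalues and the network is poised at a
    high-dimensional Hopf bifurcation. The package integrates the
    stochastic lattice dynamics under spatiotemporal white-noise drive
    (Euler-Maruyama), provides exact spectral oracles for the linear flow
    (lattice dispersion relation and FFT-based matrix-exponential
    propagator), propagates tangent-linear perturbations on top of a
    noise-driven background, and fits the input-dependent spatial
    attenuation length of the resulting activity waves. A single forced
    Hopf oscillator module illustrates the input-set relaxation timescale
    at criticality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
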