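Package: stochphase
Title: Phase Reduction of Planar Stochastic Oscillators via the Kolmogorov
    Backward Operator
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes, on a single finite-difference discretization of the
    Kolmogorov backward operator, the two standard notions of phase for
    planar noisy oscillators: the stochastic asymptotic phase (the argument
    of the slowest-decaying complex eigenfunction of the generator) and the
    mean-return-time (MRT) phase, whose isochrons are Poincare sections with
    a position-independent mean return time.  Provides sparse assembly of
    the forward (Fokker-Planck) and backward operators on rectangular grids
    with one-sided or adjoint-reflecting boundary closures, shift-invert
    Arnoldi extraction of the low-lying spectrum (stationary density,
    leading complex mode, slowest real "Floquet" mode defining stochastic
    isostables), the mean period from the stationary probability current,
    a gauge-fixed least-squares solver for the phase offset between the two
    phases, closed-form Ornstein-Uhlenbeck oracles, and an Euler-Heun
    Monte-Carlo verifier of the MRT property.  Ships the four example
    systems commonly used in the stochastic phase-reduction literature
    (spiral sink, noisy Wilson-Cowan, noisy Van der Pol, and a noisy
    heteroclinic oscillator).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    deSolve,
    jsonlite,
    Rcpp,
    methods,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
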