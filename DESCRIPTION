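Package: equiace
Title: Equivariant Atomic Cluster Expansion Potentials with Message Passing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Body-ordered, E(3)-equivariant interatomic potentials built from the
    atomic cluster expansion: real spherical harmonics, Wigner-D matrices and
    generalized Clebsch-Gordan coupling; Bessel radial features with smooth
    polynomial cutoffs; the one-particle / atomic / product / symmetrized basis
    ladder; multi-layer equivariant message passing with linear, gated and
    body-order-preserving updates; presets reproducing linear ACE, BOTNet-,
    NequIP- and SchNet-like design points; deterministic least-squares training
    on energies and forces; a verification testbench certifying equivariance,
    permutation invariance, body order, locality and cutoff smoothness; and a
    synthetic-data generator with analytic body-ordered toy potentials. Atomic
    configurations are exchanged as extended XYZ.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
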