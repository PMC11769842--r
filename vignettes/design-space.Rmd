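---
title: "Equivariant cluster-expansion potentials: model, conventions and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivariant cluster-expansion potentials: model, conventions and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the conventions that had to be fixed where
the field admits several, the synthetic data the tests run on, and what the
passing test suite does and does not establish.

## The model

An interatomic potential maps atomic positions and elements to a total
energy (eV) and forces (eV/Å). `equiace` builds such potentials as `T`
layers of equivariant message passing on the neighbourhood graph (an edge
connects atoms closer than `r_cut`), where each layer is one layer of the
atomic cluster expansion (ACE):

* **One-particle basis.** Each edge j→i carries
  `phi = R(r_ji) * Y_l1(r̂_ji) * T(h_j, theta_i, theta_j)`: a radial
  function, a real spherical harmonic of the edge direction, and an
  embedding factor. In *embedded* mode the factor is the sender's
  equivariant feature block (degree `l2`), coupled with `Y_l1` through an
  ordinary Clebsch–Gordan tensor into a definite output degree; in *delta*
  mode it is an indicator of the sender's chemical element, which recovers
  the discrete one-particle basis of classic linear ACE.
* **Atomic basis (density trick).** Summing `phi` over the neighbours of
  atom i (divided by the normalization `lambda`) gives the permutation-
  invariant A basis. Products of `nu` A-functions give the product basis:
  correlation order `nu`, body order `nu + 1` counting the central atom.
  The density trick makes this a product of sums rather than a sum over
  `nu`-tuples of neighbours; the package contains both forms and tests
  their identity to float64 round-off.
* **Symmetrized basis.** Contraction with generalized Clebsch–Gordan
  coefficients projects the product basis onto components with definite
  O(3) behaviour (degree `L`, parity). The coupling-path index `eta`
  enumerates the independent ways `nu` degrees can reach `L`.
* **Messages, updates, readouts.** Paths are combined with learnable
  weights into the message; a block-diagonal linear update mixes channels
  but never degrees; an element-conditioned residual self-connection and,
  optionally, a gated nonlinearity complete the layer. Site energies come
  from linear readouts of the invariant channels of each layer (strictly
  body-ordered), optionally plus a final nonlinear readout that represents
  the residual of the truncated body-order expansion.

Presets pin recognizable design points: `linear_ace` (T = 1, delta
embedding, full index coupling, fixed orthogonal radials), `botnet`
(nu = 1, element-dependent linear radial, linear updates, per-layer
readouts), `nequip_like` (nu = 1, agnostic MLP radial, gated silu updates,
`l_max = L_max`), `schnet_like` (everything scalar).

## Conventions the package fixes

The underlying theory leaves several conventions open; the package fixes
them once and certifies the consequences:

* **Real spherical harmonics**: orthonormal, no Condon–Shortley phase,
  components ordered m = −l..+l with sine terms on negative m, so the
  degree-1 block is proportional to (y, z, x). Evaluated by real polynomial
  recursions in the Cartesian components (complex-step safe).
* **Parity**: feature blocks carry spherical-harmonic ("natural") parity
  (−1)^L; one-particle paths are restricted to `l1 + l2 + L` even, which is
  closed under coupling and makes energies true O(3) invariants including
  reflections. The O(3)-algebra functions themselves (`wigner_D`,
  `generalized_coupling`) accept arbitrary parity labels: an improper
  operation acts as `p * D(-Q)`, and a coupling path is admissible only if
  the target parity equals the product of the input parities.
* **Coupling normalization**: path tensors follow the orthonormal
  convention (`sum_v C_eta,v C_eta',v = delta` per output component), so
  the single `nu = 1` path is exactly the identity and `nu = 2` paths carry
  textbook Clebsch–Gordan values; `clebsch_gordan()` itself is documented
  and normalized to unit Frobenius norm (the two coincide for L = 0 and
  differ by `sqrt(2L+1)` otherwise). Path order (`eta`) is lexicographic
  over the intermediates of a sequential left-to-right coupling tree; in
  embedded mode the `(Y_l1 x h_l2)` pair on each edge is pre-coupled to its
  total degree before products are formed — a recoupled but complete tree,
  spanning the same space as coupling all 2·nu indices jointly.
* **Radial basis**: `R_n(r) = sqrt(2/r_cut) sin(n pi r / r_cut) / r` with
  fixed frequencies; the polynomial envelope (power p = 6 by default)
  vanishes with two derivatives at `r_cut` and equals 1 at r = 0, and is
  applied to the Bessel features *before* any learnable map (with no output
  biases, so the zero at the cutoff survives every radial variant).
* **Weights "per atom"**: the per-atom message weights of the general
  formalism are realized as weights conditioned on the central atom's
  element — genuinely per-atom weights could not generalize across
  configurations.
* **lambda**: a single model-level constant (not per atom), estimated from
  the training set as the mean neighbour count or its square root, clamped
  at 1; both variants are exposed because they change the scale of pooled
  features and therefore extrapolation behaviour.

## Forces

Forces are exact negative gradients obtained by complex-step
differentiation: the forward pass is written entirely in real-coefficient
polynomial/analytic operations, so evaluating it on positions with an
imaginary perturbation of 1e-100 yields derivatives exact to float64
round-off (no subtractive cancellation, unlike finite differences). The
neighbour graph is held fixed during differentiation, which is valid
everywhere except exactly at a cutoff crossing, where the energy is
continuous with two vanishing derivatives. Replicated perturbed copies of a
configuration are evaluated in one disjoint-union forward pass, which keeps
the cost at roughly `3 N / batch` forward evaluations.

## Training

Models with linear readouts are linear in their readout weights and
per-element reference energies, so `fit()` builds the exact design matrix —
energy rows from the invariant features, force rows from their
complex-step position Jacobians — and solves the weighted least-squares
problem in closed form (QR with a small ridge, default 1e-10). The same
quadratic objective can be minimized by deterministic full-batch gradient
descent (`method = "gd"`) when a per-epoch training log is wanted; both
routes are bit-reproducible given the seed. Internal weights (radial,
update, embedding) keep their seeded or structured initialization: the
package treats the network as a body-ordered feature map and fits it the
way linear ACE potentials are fitted. Default loss weights (per-atom energy
1, forces 10) are a conventional choice, not tuned.

One structured initialization deserves note: `init = "product-complete"`
(for T = 2, nu = 1, element-dependent radial) assigns channel k = (a, b, l)
the Bessel function b in layer 1 and the Bessel function a on the degree-l
invariant path in layer 2, with identity updates. The layer-2 invariant
channels then span the complete tensor-product radial basis
{R_a(r1) R_b(r2) P_l(cos θ)} over chains j→i→k, so a readout-weight fit is
a least-squares problem in a *complete* three-body basis rather than a
random-features approximation. This is why the toy-potential fit below
reaches sub-percent force errors with a convex solve. The residual nonlinear
readout of the full `botnet` scheme is not convexly trainable; `fit()`
therefore targets the linear-readout variant of the preset (the "linear"
design point of the same architecture).

## Synthetic data: what it emulates and what it does not

The generator produces seeded random clusters (rejection-sampled with a
minimum pair separation, default 1.8 Å) or periodic boxes, labelled by
analytic toy potentials with exact hand-derived forces:

* `morse`: pairwise wells `D (1 - exp(-a (r - r0)))^2 - D` under the smooth
  envelope — exactly body order 2. Defaults D = 0.5 eV, a = 1.6 1/Å,
  r0 = 2.2 Å, r_cut = 4.5 Å: bond stiffness and range representative of a
  metallic dimer, and a force RMS of ~0.4 eV/Å on 8-atom clusters.
* `morse_plus_three_body`: adds
  `epsilon * cos^2(theta_jik) * g(r_ij) g(r_ik)` summed over neighbour
  pairs of each centre (epsilon = 0.15 eV, g the same polynomial envelope)
  — exactly body order 3, with an angular form a degree-2 Legendre
  expansion captures exactly.

These conditions are what the learnability tests run on: 500 training
frames of 8 atoms, 50 held-out frames. The generator's own labels are
certified — forces against finite differences, invariances, and the
inclusion–exclusion body-order functional at orders 2 and 3 — so the ground
truth of the training experiments is itself under test. What passing does
*not* show: anything about quantum-mechanical reference data (electronic
effects, many-body terms beyond order 3, label noise), about extrapolation
far outside the sampled geometry distribution, or about performance at
production scale; the toy potentials are smooth, low-body-order and
noise-free by construction.

## The verification testbench

Every defining property becomes an executable, seeded, machine-readable
check, and each check is validated *negatively* on a mutation that must
fail it:

* **Equivariance** (`check_equivariance`): features transform by the real
  Wigner matrices, energies are invariant, forces rotate as vectors, under
  sampled rotations and reflections; a coupling tensor corrupted by 1e-2
  raises deviations above 1e-3.
* **Permutation invariance** at 1e-12, with an order-dependent mock
  functional failing.
* **Body order** (`check_body_order`): the inclusion–exclusion functional
  `u(S) = sum_{A subset S} (-1)^{|S \ A|} E_centre(centre + A)` over
  neighbour subsets vanishes for `|S| >= T` iff the site energy is
  T-body. The functional automatically cancels the constant and one-body
  terms. Two-layer linear-readout models are exactly 3-body (1e-15 eV);
  a silu readout (infinite Taylor series) breaks this at ~1e-4 eV; a
  squared readout (the kernel trick, a finite Taylor expansion) doubles the
  correlation order: 5-body, with `u` vanishing from `|S| = 5`.
* **Symmetrization integral** (`brute_force_symmetrize`): the CG-built B
  basis against pure rotation averaging at 1e4 sampled O(3) operations.
  The comparison is made on the integral projected onto a seeded random
  tensor direction, whose standard error comes from its own per-rotation
  series — projecting onto the coupling tensors themselves is exactly
  invariant (zero variance) and tests nothing, while a componentwise
  3-sigma bound over thousands of correlated components would be exceeded
  even by exact code. The raw tensor is additionally held to a 6-sigma
  gross-error bound, and odd-parity functions average to zero.
* **Density trick** (`explicit_cluster_sum`): products of neighbour sums
  against explicit sums over ordered neighbour tuples, exact to 1e-12,
  with combinatorial guards (nu <= 4, <= 10 neighbours).
* **Locality** (`check_locality`): site energies of atoms farther than T
  hops from a displaced probe change by *exactly* zero (bitwise), because
  the canonical edge ordering makes unaffected summations bit-identical;
  a chain of atoms spaced 0.9 r_cut shows influence reaching exactly T
  hops — the receptive field T × r_cut.
* **Cutoff smoothness** (`check_cutoff_smoothness`): the energy along a
  dimer path crossing r_cut in 1e-4 Å steps jumps by less than 1e-8 eV
  (observed ~1e-13). The path is a dimer deliberately: with more
  interacting atoms the adjacent-sample differences are dominated by
  genuine smooth variation of order |dE/ds|·step, which the jump budget is
  not meant to bound. The hard-cutoff mutation is detected at ~1e-6 eV;
  note that with the sine Bessel basis all radial features vanish at r_cut
  anyway, so a hard envelope produces a derivative discontinuity rather
  than an O(1) energy jump — still four orders of magnitude above the
  smooth signature.
* **Design-space reductions**: the generic product/symmetrize engine at
  nu = 1 equals the directly-coded ordinary-CG convolution to 1e-12 (they
  share no code path for the coupling order), and the T = 1 delta-mode
  model equals an independent evaluation that bypasses the density trick
  entirely (explicit cluster sums per atom) to 1e-10.

## Numerical choices

* Float64 throughout; energies in eV, lengths in Å.
* Coupling coefficients from the Racah closed form in the complex basis,
  transformed to the real basis, phase-fixed to be real and sign-fixed
  deterministically; cached in memory, with an optional versioned on-disk
  layer under `options(equiace.cache_dir = ...)` (layout `v1/<key>.rds`).
* Neighbour lists by brute-force O(n^2) search with explicit cell
  replication — exact by construction at desk scale; edges strictly inside
  `r_cut` (consistent with the envelope's zero there) and canonically
  sorted so all aggregations are bit-reproducible.
* Spherical quadrature (Gauss–Legendre × uniform azimuth) for the
  orthonormality tests: exact for band-limited integrands, so tolerances
  sit at 1e-10 rather than Monte-Carlo noise levels.
* Problem sizes in the shipped tests: models with 4-6 channels and 4
  Bessel functions for the symmetry/locality/smoothness certificates;
  the learnability experiment uses n_basis = 6, n_channels = 108
  (= 6² × 3 product-complete channels), 500 training frames of 8 atoms.
  These sizes were chosen so the full certificate suite completes in
  minutes on a single core while every property is still exercised at
  nontrivial angular resolution (l up to 2, degrees up to 4 in the
  coupling oracle).
* Degenerate inputs: isolated atoms give exactly the reference plus
  one-body constant with zero forces; atoms closer than 1e-6 Å are
  rejected; rank-deficient reference-energy systems fall back to the
  minimum-norm solution with a warning; `lambda` is clamped at 1 for
  neighbour-poor data.

## Known limitations

* `fit()` optimizes output weights only; internal radial/update weights
  stay at initialization (structured or random). Nonconvex end-to-end
  training is out of scope.
* Embedded-mode products at nu >= 2 enumerate degree tuples only (the
  uncoupled-channel regime); the fully-coupled polynomial-degree truncation
  applies to delta mode.
* No stress/virial outputs, no molecular-dynamics integration, no
  long-range electrostatics, and no claim of fidelity to any published
  trained model's hyperparameters; presets are faithful to design points,
  not to specific experiments.
* The attention-augmented one-particle basis and Cartesian-feature model
  families are not implemented.
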