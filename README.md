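# equiace

Body-ordered, E(3)-equivariant interatomic potentials in R, built on the
atomic cluster expansion (ACE) and equivariant message passing — together
with a verification testbench that turns the defining properties of such
potentials (equivariance, permutation invariance, body order, locality,
cutoff smoothness) into executable certificates, and a synthetic-data
generator with analytic body-ordered toy potentials so everything runs
without external data.

## Who this is for

Researchers in molecular modelling and machine-learned force fields who want
a transparent, fully-inspectable reference implementation of the
ACE / equivariant-message-passing design space — for teaching, for testing
conventions (real spherical harmonics, Wigner-D matrices, generalized
Clebsch–Gordan coupling), or for certifying properties of model variants at
desk scale. It is a laboratory, not a production MD engine.

## The model

A configuration of atoms at positions **r**_i with elements z_i is mapped to
a total energy

```
E = sum_z n_z E0_z + sum_i sum_t R_t(sigma_i^(t))  (+ E_rest)
```

by `T` layers of equivariant message passing. Each layer is one layer of
equivariant ACE:

1. **One-particle basis** on each edge (j → i):
   `phi_kvL = R_kcl1L(r_ji) * Y_l1m1(r̂_ji) * T_kcL(h_j, theta_i, theta_j)`,
   a learnable radial function (Bessel features under a smooth polynomial
   cutoff) times a real spherical harmonic times an embedding of the
   sender's features/elements.
2. **Density trick**: pooling over neighbours gives the atomic basis
   `A_i,kv = (1/lambda) * sum_j phi_kv`, and products of `nu` A-functions
   give the product basis `prod_xi A_i,kv_xi` — correlation order `nu`,
   body order `nu + 1`.
3. **Symmetrization**: contraction with generalized Clebsch–Gordan
   coefficients `C^LM_eta,v` yields the B basis with definite O(3)
   behaviour; `eta` enumerates the independent coupling paths.
4. **Message and update**: `m_i,kLM = sum_eta w_keta L B_i,keta,LM`,
   followed by a block-diagonal linear update (no mixing across L or M), an
   element-conditioned self-connection, and optionally a gated nonlinearity.
5. **Readout**: linear maps of the invariant (L = 0) channels give
   body-ordered per-layer site energies; an optional final nonlinear readout
   captures the residual of the body-order expansion.

Choosing `T`, `nu`, `l_max`, `L_max`, the embedding and the coupling mode
reproduces familiar design points, available as presets: `linear_ace`
(T = 1, discrete element labels, full index coupling), `botnet` (nu = 1,
element-dependent radial, strictly linear updates, body-ordered readouts),
`nequip_like` (nu = 1, gated updates, MLP radial) and `schnet_like` (scalar
convolutions). Forces are exact gradients, computed by complex-step
differentiation of the forward pass (machine-precision derivatives).

## Worked example

```r
library(equiace)

# synthetic dataset: Morse pairs + an explicit three-body angular term,
# with exact analytic forces
spec <- toy_potential_spec("morse_plus_three_body",
                           D = 0.5, a = 1.6, r0 = 2.2, epsilon = 0.15,
                           r_cut = 4.5)
ds <- make_dataset(spec, counts = 550, n_atoms = 8, elements = 29,
                   split_fractions = c(500/550, 0, 50/550), seed = 42)

# a body-ordered two-layer potential (BOTNet-style design point)
cfg <- model_config("botnet", elements = 29, r_cut = 4.5, T = 2,
                    n_channels = 108, n_basis = 6, l_max = 2, L_max = 2,
                    readout = "per_layer_linear", init = "product-complete",
                    seed = 3)
model <- assemble_model(cfg)

# deterministic least-squares fit on energies and forces
st <- fit(model, ds$train, NULL, optimizer_cfg = list(ridge = 1e-9), seed = 5)
evaluate_errors(st$model, ds$test)
#> $energy_rmse          0.000234   (eV/atom)
#> $force_rmse           0.00233    (eV/A)
#> $force_rms_label      0.365      (eV/A)
#> $force_rmse_relative  0.00638

# certify the fitted model's body order: site energies are exactly 3-body
site_fn <- function(pos, zs)
  total_energy(st$model, atomic_configuration(pos, zs))$site_energies[1]
check_body_order(site_fn, list(position = c(0,0,0), z = 29),
                 list(positions = rbind(c(2,0,0), c(0,2,0), c(0,0,2)),
                      z = rep(29, 3)),
                 claimed_order = 3, r_cut = 4.5)
#> [PASS] body_order: max deviation 1.8e-15 (tol 1.0e-09)
```

The fitted two-layer model reaches a held-out force error of 0.64% of the
label force RMS: the chain-structured layer-2 features span exactly the
three-body terms the toy potential contains, and the fit is a convex
least-squares problem in the readout weights.

Other entry points: `read_extxyz()`/`write_extxyz()` for extended-XYZ
exchange, `spherical_harmonics()`, `wigner_D()`, `clebsch_gordan()` and
`generalized_coupling()` for the O(3) algebra, `check_equivariance()`,
`check_permutation_invariance()`, `check_locality()`,
`check_cutoff_smoothness()` and `brute_force_symmetrize()` for the
testbench, and `exec/equiace` for a command-line
`train | eval | verify | make-data` interface.

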