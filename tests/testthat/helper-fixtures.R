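# Shared fixtures: tiny seeded configurations and models, built once per
# test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = fixture_env, inherits = FALSE)) {
    assign(key, builder(), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# Seeded clusters with 2 elements, 5-7 atoms.
small_configs <- function(n = 3, seed = 11) {
  memo(paste0("cfgs_", n, "_", seed), function() {
    random_configurations(n, 6, c(1, 29), min_separation = 1.7, seed = seed)
  })
}

# A small BOTNet-architecture model with per-layer linear readouts.
small_botnet <- function(readout = "per_layer_linear", seed = 3) {
  memo(paste0("botnet_", readout, "_", seed), function() {
    cfg <- model_config("botnet", elements = c(1, 29), r_cut = 4, T = 2,
                        n_channels = 6, n_basis = 4, l_max = 2, L_max = 2,
                        readout = readout, seed = seed)
    assemble_model(cfg)
  })
}

small_linear_ace <- function(nu = 2, seed = 2) {
  memo(paste0("lace_", nu, "_", seed), function() {
    cfg <- model_config("linear_ace", elements = 29, r_cut = 4, nu = nu,
                        l_max = 2, n_basis = 3, max_poly_degree = 7,
                        seed = seed)
    assemble_model(cfg)
  })
}

# Single-element cluster frames labelled with the Morse + three-body toy
# potential.
toy_spec <- function() {
  toy_potential_spec("morse_plus_three_body", D = 0.5, a = 1.6, r0 = 2.2,
                     epsilon = 0.15, r_cut = 4.5)
}

labelled_frames <- function(n = 20, seed = 42) {
  memo(paste0("labelled_", n, "_", seed), function() {
    cfs <- random_configurations(n, 8, 29, min_separation = 1.8, seed = seed)
    lapply(cfs, label_config, spec = toy_spec())
  })
}

# Site-energy functional of the centre atom for a model (centre = row 1).
model_site_fn <- function(model) {
  function(pos, zs) {
    total_energy(model, atomic_configuration(pos, zs))$site_energies[1]
  }
}

# A fixed neighbour pool inside r_cut = 4 of the origin.
body_order_pool <- function(n = 5) {
  pos <- rbind(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(-1.5, 1.5, 0),
               c(1.4, 1.4, 0.2), c(-1, -1, 1))
  list(positions = pos[seq_len(n), , drop = FALSE], z = rep(29, n))
}

expect_report_pass <- function(report) {
  expect_s3_class(report, "verification_report")
  expect_true(report$pass,
              label = sprintf("%s (max dev %.3e, tol %.1e)", report$name,
                              report$max_deviation, report$tolerance))
}
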