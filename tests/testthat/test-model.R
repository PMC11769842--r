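# Model assembly: updates, self-connection, gates, readouts, energy, forces,
# presets and their structural invariants.

test_that("linear update is structurally block diagonal", {
  set.seed(4)
  m <- list("0" = array(rnorm(12), c(2, 3, 1)),
            "1" = array(rnorm(18), c(2, 3, 3)))
  W <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  Wid <- W; Wid[, , 1] <- diag(3); Wid[, , 2] <- diag(3)
  out_id <- linear_update(m, Wid)
  expect_equal(out_id, m, tolerance = 1e-14)
  # zeroing the L = 1 block changes only the L = 1 output
  Wz <- W; Wz[, , 2] <- 0
  full <- linear_update(m, W)
  part <- linear_update(m, Wz)
  expect_equal(part[["0"]], full[["0"]])
  expect_true(all(part[["1"]] == 0))
  expect_error(linear_update(m, W[, , 1, drop = FALSE]), "mismatch")
})

test_that("self-connection carries state and respects elements", {
  attrs <- one_hot_attributes(c(1L, 29L), c(1L, 29L))
  h_prev <- list("0" = array(c(1, 2, 3, 4), c(2, 2, 1)))
  upd <- list("0" = array(0, c(2, 2, 1)))
  S0 <- lapply(1:2, function(z) array(0, c(2, 2, 1)))
  expect_equal(self_connection(upd, h_prev, attrs, S0), upd)
  Sid <- lapply(1:2, function(z) {
    a <- array(0, c(2, 2, 1)); a[, , 1] <- diag(2); a
  })
  expect_equal(self_connection(upd, h_prev, attrs, Sid), h_prev)
})

test_that("gated nonlinearities act on scalars and gate equivariants", {
  set.seed(5)
  h <- list("0" = array(rnorm(6), c(2, 3, 1)),
            "2" = array(rnorm(30), c(2, 3, 5)))
  expect_identical(gated_nonlinearity(h, "none"), h)
  hs <- gated_nonlinearity(h, "silu")
  expect_equal(hs[["0"]][, , 1], equiace:::silu(h[["0"]][, , 1]))
  hq <- gated_nonlinearity(h, "square")
  expect_equal(hq[["0"]][, , 1], h[["0"]][, , 1]^2)
  expect_equal(hq[["2"]][1, 2, ], h[["2"]][1, 2, ] * h[["0"]][1, 2, 1])
  expect_error(gated_nonlinearity(h, "exp"))
})

test_that("readout schemes: zeros, single layer, nonlinear variants", {
  states <- list(list("0" = array(1:4 / 2, c(2, 2, 1))),
                 list("0" = array(4:1 / 2, c(2, 2, 1))))
  par0 <- list(readout = list(c(0, 0), c(0, 0)))
  expect_true(all(readout(states, "linear", par0) == 0))
  par1 <- list(readout = list(NULL, c(1, -1)))
  r1 <- readout(states, "linear", par1)
  expect_equal(ncol(r1), 1L)
  expect_equal(as.numeric(r1), as.numeric(states[[2]][["0"]][, 1, 1] -
                                            states[[2]][["0"]][, 2, 1]))
  par2 <- list(readout = list(NULL, c(1, -1)))
  expect_equal(as.numeric(readout(states, "square", par2)),
               as.numeric(r1)^2)
})

test_that("preset configurations enforce their design points", {
  expect_error(model_config("custom", elements = 29, embedding = "delta",
                            coupling = "uncoupled"), "full coupling")
  expect_error(model_config("custom", elements = 29, embedding = "learned",
                            coupling = "full"), "delta")
  expect_error(model_config("botnet", elements = 29, nonlinearity = "silu"),
               "linear")
  expect_error(model_config("nequip_like", elements = 29, l_max = 2,
                            L_max = 1), "l_max = L_max")
  lace <- model_config("linear_ace", elements = c(1, 29))
  expect_equal(lace$T, 1L)
  expect_equal(lace$embedding, "delta")
  expect_equal(lace$coupling, "full")
  bn <- model_config("botnet", elements = 29)
  expect_equal(bn$nu, 1L)
  expect_equal(bn$readout, "botnet")
  nq <- model_config("nequip_like", elements = 29)
  expect_equal(nq$l_max, nq$L_max)
  sc <- model_config("schnet_like", elements = 29)
  expect_equal(c(sc$l_max, sc$L_max), c(0L, 0L))
})

test_that("isolated atoms: reference energy only, zero forces", {
  model <- small_botnet()
  model$params$e0[] <- c(-1.5, -3.25)
  cf <- atomic_configuration(matrix(c(0, 0, 0), 1, 3), 29L)
  res <- total_energy(model, cf)
  # E = reference + the network's one-body constant, independent of position
  expect_equal(res$e0, -3.25, tolerance = 1e-12)
  cf_far <- atomic_configuration(matrix(c(7, -2, 1), 1, 3), 29L)
  expect_equal(total_energy(model, cf_far)$energy, res$energy,
               tolerance = 1e-12)
  shifted <- model; shifted$params$e0[2] <- -4.25
  expect_equal(total_energy(shifted, cf)$energy, res$energy - 1,
               tolerance = 1e-12)
  expect_equal(compute_forces(model, cf), matrix(0, 1, 3))
  expect_error(total_energy(model, atomic_configuration(diag(3) * 5,
                                                        c(3L, 3L, 3L))),
               "element")
})

test_that("energy is size extensive for well-separated replicas", {
  model <- small_botnet()
  cf <- small_configs()[[1]]
  res1 <- total_energy(model, cf)
  far <- cf$positions + matrix(c(50, 0, 0), nrow(cf$positions), 3,
                               byrow = TRUE)
  cf2 <- atomic_configuration(rbind(cf$positions, far),
                              rep(cf$atomic_numbers, 2))
  res2 <- total_energy(model, cf2)
  expect_equal(res2$energy, 2 * res1$energy, tolerance = 1e-10)
  expect_equal(res2$site_energies[seq_len(nrow(cf$positions))],
               res1$site_energies, tolerance = 1e-12)
})

test_that("energy is invariant and forces rotate under O(3) + translations", {
  for (model in list(small_botnet(), small_linear_ace())) {
    cf <- small_configs()[[1]]
    if (model$config$embedding == "delta") {
      cf$atomic_numbers <- rep(29L, length(cf$atomic_numbers))
    }
    E <- function(cfx) total_energy(model, cfx)$energy
    expect_report_pass(check_equivariance(E, cf, n_rotations = 10, seed = 7,
                                          tolerance = 1e-10))
    cf_t <- cf
    cf_t$positions <- cf_t$positions +
      matrix(c(3, -1, 9), nrow(cf$positions), 3, byrow = TRUE)
    expect_equal(E(cf_t), E(cf), tolerance = 1e-11)
    Ffun <- function(cfx) compute_forces(model, cfx)
    expect_report_pass(check_equivariance(Ffun, cf, n_rotations = 3, seed = 8,
                                          tolerance = 1e-9))
  }
})

test_that("complex-step forces match central finite differences", {
  for (model in list(small_botnet("botnet"), small_linear_ace())) {
    cf <- small_configs()[[3]]
    if (model$config$embedding == "delta") {
      cf$atomic_numbers <- rep(29L, length(cf$atomic_numbers))
    }
    Fa <- compute_forces(model, cf)
    expect_lt(max(abs(colSums(Fa))), 1e-10)  # translation invariance
    h <- 1e-4
    nat <- nrow(cf$positions)
    fd <- matrix(0, nat, 3)
    for (a in seq_len(nat)) for (d in 1:3) {
      cp <- cf; cp$positions[a, d] <- cp$positions[a, d] + h
      cm <- cf; cm$positions[a, d] <- cm$positions[a, d] - h
      fd[a, d] <- -(total_energy(model, cp)$energy -
                      total_energy(model, cm)$energy) / (2 * h)
    }
    expect_lt(max(abs(Fa - fd)), 1e-6)
    expect_error(compute_forces(model, atomic_configuration(
      matrix(0, 2, 3), rep(29L, 2))), "overlapping")
  }
})

test_that("nonlinear presets stay equivariant (gates, MLP radial)", {
  cfg <- model_config("nequip_like", elements = c(1, 29), r_cut = 4, T = 2,
                      n_channels = 4, n_basis = 4, l_max = 1, L_max = 1,
                      seed = 6)
  model <- assemble_model(cfg)
  cf <- small_configs()[[2]]
  E <- function(cfx) total_energy(model, cfx)$energy
  expect_report_pass(check_equivariance(E, cf, n_rotations = 8, seed = 9,
                                        tolerance = 1e-10))
  cfg_s <- model_config("schnet_like", elements = c(1, 29), r_cut = 4, T = 2,
                        n_channels = 4, n_basis = 4, seed = 6)
  model_s <- assemble_model(cfg_s)
  Es <- function(cfx) total_energy(model_s, cfx)$energy
  expect_report_pass(check_equivariance(Es, cf, n_rotations = 8, seed = 10,
                                        tolerance = 1e-10))
})

test_that("nu = 2 embedded engine produces an equivariant potential", {
  cfg <- model_config("custom", elements = 29, r_cut = 4, T = 1, nu = 2,
                      n_channels = 3, n_basis = 3, l_max = 1, L_max = 1,
                      embedding = "learned", radial_mode = "element-dependent",
                      coupling = "uncoupled", seed = 12)
  model <- assemble_model(cfg)
  cf <- small_configs()[[1]]
  cf$atomic_numbers <- rep(29L, length(cf$atomic_numbers))
  E <- function(cfx) total_energy(model, cfx)$energy
  expect_report_pass(check_equivariance(E, cf, n_rotations = 6, seed = 11,
                                        tolerance = 1e-10))
})

test_that("models round trip through the plain-text directory format", {
  model <- small_botnet()
  dir <- tempfile("model")
  write_model(model, dir)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- read_model(dir)
  cf <- small_configs()[[1]]
  expect_equal(total_energy(back, cf)$energy, total_energy(model, cf)$energy,
               tolerance = 1e-12)
})
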