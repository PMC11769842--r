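# The ACE ladder: one-particle basis, A basis, product basis, symmetrized
# basis and message formation.

# A tiny delta-mode A basis around a single centre for oracle comparisons.
delta_A_fixture <- function(n_nb = 4, l_max = 2, n_basis = 2, seed = 17) {
  pos <- with_seed_positions(n_nb, seed)
  cf <- atomic_configuration(rbind(c(0, 0, 0), pos), rep(29, n_nb + 1))
  nl <- build_neighbour_list(cf, 4)
  rc <- radial_config(r_cut = 4, n_basis = n_basis)
  attrs <- one_hot_attributes(cf$atomic_numbers, 29L)
  h <- initial_embedding(attrs, matrix(1, 1, 1))
  Rb <- equiace:::enveloped_bessel(nl$distances, rc)
  eb <- one_particle_basis(0L, nl, list(h = h, attrs = attrs), Rb,
                           list(l_max = l_max, L_max = l_max, mode = "delta"))
  A <- pool_atomic_basis(eb, nl$receivers, 1, n_nb + 1)
  list(cf = cf, nl = nl, eb = eb, A = A, rc = rc)
}

with_seed_positions <- function(n, seed) {
  equiace:::with_seed(seed, {
    matrix(stats::rnorm(3 * n), n, 3) * 0.8 +
      matrix(c(1.6, 0, 0), n, 3, byrow = TRUE)
  })
}

test_that("initial embedding reduces to one-hot rows for identity weights", {
  attrs <- one_hot_attributes(c(1L, 29L, 29L), c(1L, 29L))
  h <- initial_embedding(attrs, diag(2))
  expect_equal(h[["0"]][, , 1], attrs$one_hot)
  # same element, same embedding; zero weights, zero features
  hw <- initial_embedding(attrs, matrix(c(0.3, -1, 2, 0.5), 2, 2))
  expect_equal(hw[["0"]][2, , ], hw[["0"]][3, , ])
  expect_true(all(initial_embedding(attrs, matrix(0, 2, 5))[["0"]] == 0))
  expect_error(initial_embedding(attrs, matrix(0, 3, 5)), "n_elements")
})

test_that("delta one-particle basis is R_n * indicator * Y_lm", {
  fx <- delta_A_fixture()
  nl <- fx$nl; eb <- fx$eb
  rc <- fx$rc
  edges_to_centre <- which(nl$receivers == 1)
  Rb <- equiace:::enveloped_bessel(nl$distances, rc)
  unit <- nl$displacements / nl$distances
  Y <- equiace:::sh_matrix(unit, 2)
  q <- which(eb$entries$n == 2 & eb$entries$l == 1)
  expect_equal(eb$values[[q]][edges_to_centre, 1, ],
               Rb[edges_to_centre, 2] * Y[edges_to_centre, equiace:::sh_cols(1)],
               tolerance = 1e-14)
})

test_that("A basis: empty neighbourhood, single neighbour, edge-order", {
  cf <- atomic_configuration(rbind(c(0, 0, 0), c(2, 0, 0), c(20, 0, 0)),
                             rep(29, 3))
  nl <- build_neighbour_list(cf, 4)
  rc <- radial_config(r_cut = 4, n_basis = 2)
  attrs <- one_hot_attributes(cf$atomic_numbers, 29L)
  h <- initial_embedding(attrs, matrix(1, 1, 1))
  Rb <- equiace:::enveloped_bessel(nl$distances, rc)
  eb <- one_particle_basis(0L, nl, list(h = h, attrs = attrs), Rb,
                           list(l_max = 1, L_max = 1, mode = "delta"))
  lam <- 2.5
  A <- pool_atomic_basis(eb, nl$receivers, lam, 3)
  # atom 3 is isolated: A identically zero
  for (v in A$values) expect_true(all(v[3, , ] == 0))
  # atom 1 has one neighbour: A = phi / lambda
  e1 <- which(nl$receivers == 1)
  for (q in seq_along(A$values)) {
    expect_equal(A$values[[q]][1, , ], eb$values[[q]][e1, , ] / lam,
                 tolerance = 1e-14)
  }
  expect_error(pool_atomic_basis(eb, nl$receivers, 0, 3))
})

test_that("product basis: nu=1 slice equals A; squares on the diagonal", {
  fx <- delta_A_fixture()
  PB1 <- product_basis(fx$A, 1)
  for (i in seq_along(PB1$values)) {
    expect_equal(PB1$values[[i]], fx$A$values[[PB1$tuples[[i]][1]]])
  }
  # scalar entry squared on the diagonal tuple
  q0 <- which(fx$eb$entries$l == 0)[1]
  PB2 <- product_basis(fx$A, 2, tuple_index_set = list(c(q0, q0)))
  a <- fx$A$values[[q0]][, 1, 1]
  expect_equal(PB2$values[[1]][, 1, 1], a^2, tolerance = 1e-14)
  expect_error(product_basis(fx$A, 0), "nu")
})

test_that("density trick: products of sums equal explicit cluster sums", {
  fx <- delta_A_fixture(n_nb = 5)
  sel <- which(fx$nl$receivers == 1)
  phi <- lapply(fx$eb$values, function(v) {
    matrix(v[sel, 1, ], length(sel), dim(v)[3])
  })
  for (nu in 1:3) {
    tuples <- equiace:::sorted_tuples(length(phi), nu)
    keep <- sample(seq_along(tuples), 5)  # spot-check a handful per order
    PB <- product_basis(fx$A, nu, tuple_index_set = tuples[keep])
    oracle <- explicit_cluster_sum(phi, nu, tuples = tuples[keep])
    for (k in seq_along(keep)) {
      expect_lt(max(abs(PB$values[[k]][1, 1, ] - oracle[[k]])), 1e-12)
    }
  }
})

test_that("symmetrize: nu=1 identity, L=0 rotation invariance", {
  fx <- delta_A_fixture()
  PB1 <- product_basis(fx$A, 1)
  SB <- symmetrize(PB1, 1L)
  # single identity path per degree-1 tuple: B = A
  expect_true(all(fx$eb$entries$l[unlist(PB1$tuples[SB$index$tuple])] == 1))
  for (k in seq_len(nrow(SB$index))) {
    tp <- PB1$tuples[[SB$index$tuple[k]]]
    expect_equal(SB$values[[k]], fx$A$values[[tp[1]]], tolerance = 1e-14)
  }
  # L = 0 components of nu = 2 products are rotation invariant
  PB2 <- product_basis(fx$A, 2)
  SB0 <- symmetrize(PB2, 0L)
  Q <- random_rotations(1, seed = 31)[[1]]
  fxr <- local({
    cfr <- equiace:::rotate_config(fx$cf, Q)
    nl <- build_neighbour_list(cfr, 4)
    attrs <- one_hot_attributes(cfr$atomic_numbers, 29L)
    h <- initial_embedding(attrs, matrix(1, 1, 1))
    Rb <- equiace:::enveloped_bessel(nl$distances, fx$rc)
    eb <- one_particle_basis(0L, nl, list(h = h, attrs = attrs), Rb,
                             list(l_max = 2, L_max = 2, mode = "delta"))
    A <- pool_atomic_basis(eb, nl$receivers, 1, nrow(cfr$positions))
    symmetrize(product_basis(A, 2), 0L)
  })
  for (k in seq_along(SB0$values)) {
    expect_lt(max(abs(SB0$values[[k]] - fxr$values[[k]])), 1e-10)
  }
  expect_error(symmetrize(PB2, 0L, coupling = list(generalized_coupling(5L, 5L))),
               "degrees")
})

test_that("symmetrized B agrees with the Monte-Carlo rotation average", {
  # invariant case: averaging the product basis over O(3) projects exactly
  # onto the CG-built B functions
  pos <- with_seed_positions(4, 23)
  rc <- radial_config(r_cut = 4, n_basis = 1)
  degrees <- c(1, 1)
  Afun <- function(P) {
    r <- equiace:::row_norms(P)
    Rb <- equiace:::enveloped_bessel(r, rc)[, 1]
    Y <- equiace:::sh_matrix(P / r, 2)
    A1 <- colSums(Rb * Y[, equiace:::sh_cols(degrees[1]), drop = FALSE])
    A2 <- colSums(Rb * Y[, equiace:::sh_cols(degrees[2]), drop = FALSE])
    as.vector(outer(A1, A2))
  }
  for (L in c(0L, 2L)) {
    mc <- brute_force_symmetrize(Afun, pos, degrees, L, n_rotations = 4000,
                                 seed = 5)
    gc <- generalized_coupling(degrees, L)
    Av <- Afun(pos)
    pred <- matrix(0, length(Av), 2 * L + 1)
    M0 <- L + 1L
    for (e in seq_along(gc$tensors)) {
      Ct <- matrix(gc$tensors[[e]], length(Av), 2 * L + 1)
      B <- as.numeric(Av %*% Ct)
      pred <- pred + Ct * B[M0]
    }
    pred <- pred / (2 * L + 1)
    expect_lt(max(abs(mc$estimate - pred) / pmax(mc$se, 1e-12)), 4)
  }
  # parity cancellation: an odd-parity function averages to zero under O(3)
  odd <- function(P) sum(P[, 1] * P[, 2] * P[, 3] / equiace:::row_norms(P)^2)
  mc0 <- brute_force_symmetrize(function(P) odd(P), pos, degrees = 0L, L = 0L,
                                n_rotations = 4000, seed = 7)
  expect_lt(abs(mc0$estimate[1, 1]), 3 * mc0$se[1, 1] + 1e-12)
})

test_that("form_message weights and the nu=1 fast path agree", {
  fx <- delta_A_fixture()
  PB <- product_basis(fx$A, 2)
  SB <- symmetrize(PB, 0L)
  nb <- length(SB$values)
  m0 <- form_message(SB, matrix(0, 1, nb))
  expect_true(all(m0 == 0))
  w1 <- matrix(0, 1, nb); w1[1, 3] <- 2.5
  expect_equal(form_message(SB, w1), 2.5 * SB$values[[3]])
  expect_error(form_message(SB, lapply(1:1, function(z) w1)), "attributes")
})

test_that("generic nu=1 engine reproduces the direct convolution", {
  model <- small_botnet()
  cfgm <- model$config
  cf <- small_configs()[[2]]
  attrs <- one_hot_attributes(cf$atomic_numbers, cfgm$elements)
  nl <- build_neighbour_list(cf, cfgm$r_cut)
  h <- initial_embedding(attrs, model$params$embedding)
  paths <- model$params$layers[[1]]$paths
  rc <- equiace:::model_radial_config(cfgm, nrow(paths))
  R <- element_dependent_radial(nl$distances, attrs$indices[nl$senders],
                                model$params$layers[[1]]$radial, rc)
  lam <- 1.7
  m_direct <- nequip_convolution(nl, list(h = h), R, cfgm$l_max, cfgm$L_max,
                                 lambda = lam)
  eb <- one_particle_basis(0L, nl, list(h = h, attrs = attrs), R,
                           list(l_max = cfgm$l_max, L_max = cfgm$L_max,
                                mode = "embedded"))
  A <- pool_atomic_basis(eb, nl$receivers, lam, nrow(cf$positions))
  PB <- product_basis(A, 1)
  for (L in 0:cfgm$L_max) {
    SB <- symmetrize(PB, L)
    m_gen <- form_message(SB, matrix(1, cfgm$n_channels, length(SB$values)))
    expect_lt(max(abs(m_gen - m_direct[[as.character(L)]])), 1e-12)
  }
  # SchNet collapse: l_max = L_max = 0 is a scalar convolution
  R0 <- R[, , 1, drop = FALSE]
  m_sc <- nequip_convolution(nl, list(h = h), R0, 0L, 0L, lambda = lam)
  P <- equiace:::pooling_matrix(nl$receivers, nrow(cf$positions))
  h0 <- h[["0"]][nl$senders, , 1]
  manual <- (P %*% (as.vector(R0[, , 1] / sqrt(4 * pi)) * h0)) / lam
  expect_equal(m_sc[["0"]][, , 1], manual, tolerance = 1e-13)
  # zero sender features give a zero message
  hz <- list("0" = h[["0"]] * 0)
  mz <- nequip_convolution(nl, list(h = hz), R, cfgm$l_max, cfgm$L_max)
  expect_true(all(vapply(mz, function(x) all(x == 0), TRUE)))
})

test_that("messages are permutation invariant and equivariant", {
  model <- small_botnet()
  cf <- small_configs()[[1]]
  fn_site <- function(cfx) total_energy(model, cfx)$site_energies
  expect_report_pass(check_permutation_invariance(fn_site, cf,
                                                  n_shuffles = 6, seed = 2))
  fn_feat <- function(cfx) {
    equiace:::model_forward(model, cfx, store_states = TRUE)$states[[2]]
  }
  expect_report_pass(check_equivariance(fn_feat, cf, n_rotations = 10,
                                        seed = 3, tolerance = 1e-10))
})
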