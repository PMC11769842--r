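# Synthetic data: configuration sampling, toy-potential labels with exact
# forces, dimer curves and dataset splitting.

test_that("random configurations are seeded, separated and counted", {
  a <- random_configurations(4, 7, c(1, 29), min_separation = 1.6, seed = 9)
  b <- random_configurations(4, 7, c(1, 29), min_separation = 1.6, seed = 9)
  expect_identical(a, b)
  expect_length(a, 4L)
  for (cf in a) {
    expect_equal(nrow(cf$positions), 7L)
    expect_gte(min(dist(cf$positions)), 1.6)
    expect_true(all(cf$atomic_numbers %in% c(1L, 29L)))
  }
  c2 <- random_configurations(2, 4, 29, mode = "box", min_separation = 1.5,
                              seed = 3)
  expect_false(is.null(c2[[1]]$cell))
  expect_error(random_configurations(1, 50, 29, min_separation = 10,
                                     radius = 3, max_tries = 5),
               "min_separation")
})

test_that("Morse labels: well depth, reciprocity and exact forces", {
  spec <- toy_potential_spec("morse", D = 0.5, a = 1.6, r0 = 2.2, r_cut = 30)
  dimer <- dimer_curve(c(29, 29), c(2.2))[[1]]
  lab <- morse_labels(dimer, spec)
  expect_equal(lab$energy, -spec$D, tolerance = 1e-4)  # f_env(r0) ~ 1
  expect_equal(lab$forces[1, ], -lab$forces[2, ], tolerance = 1e-12)
  cf <- labelled_frames(1)[[1]]
  spec3 <- toy_spec()
  lab3 <- three_body_labels(cf, spec3)
  h <- 1e-5
  fd <- matrix(0, nrow(cf$positions), 3)
  for (a in seq_len(nrow(cf$positions))) for (d in 1:3) {
    cp <- cf; cp$positions[a, d] <- cp$positions[a, d] + h
    cm <- cf; cm$positions[a, d] <- cm$positions[a, d] - h
    fd[a, d] <- -(three_body_labels(cp, spec3)$energy -
                    three_body_labels(cm, spec3)$energy) / (2 * h)
  }
  expect_lt(max(abs(lab3$forces - fd)), 1e-8)
  expect_error(morse_labels(atomic_configuration(matrix(0, 2, 3),
                                                 c(29L, 29L)), spec),
               "overlap")
})

test_that("three-body angular form: collinear and right-angle geometries", {
  spec <- toy_potential_spec("morse_plus_three_body", D = 0.5, a = 1.6,
                             r0 = 2.2, epsilon = 0.15, r_cut = 10)
  g <- function(r) equiace:::cutoff_value(r, spec$r_cut, spec$p)
  # collinear triple (theta = pi): cos^2 = 1, term = eps * g * g
  col <- atomic_configuration(rbind(c(0, 0, 0), c(2, 0, 0), c(-2, 0, 0)),
                              rep(29L, 3))
  pair_part <- morse_labels(col, spec)$energy
  e3 <- three_body_labels(col, spec)$energy - pair_part
  # triplets centred at the end atoms contribute too (theta = 0, cos^2 = 1)
  expect_equal(e3, spec$epsilon * (g(2)^2 + 2 * g(2) * g(4)),
               tolerance = 1e-10)
  # right angle at the centre: that triplet vanishes
  ra <- atomic_configuration(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                             rep(29L, 3))
  e3_ra <- three_body_labels(ra, spec)$energy - morse_labels(ra, spec)$energy
  cth <- 4 / (2 * sqrt(8))  # cos of the base angles of the right triangle
  expect_equal(e3_ra, 2 * spec$epsilon * cth^2 * g(2) * g(sqrt(8)),
               tolerance = 1e-10)
})

test_that("generator labels are certified at their declared body orders", {
  for (case in list(list(kind = "morse", order = 2),
                    list(kind = "morse_plus_three_body", order = 3))) {
    spec <- toy_potential_spec(case$kind, D = 0.5, a = 1.6, r0 = 2.2,
                               epsilon = 0.15, r_cut = 4.5)
    labeller <- if (case$kind == "morse") morse_labels else three_body_labels
    etot <- function(pos, zs) {
      if (nrow(pos) < 2) return(0)
      labeller(atomic_configuration(pos, zs), spec)$energy
    }
    # interaction energy of the centre: total minus the pool-only part
    site_fn <- function(pos, zs) {
      etot(pos, zs) - if (nrow(pos) > 1) {
        etot(pos[-1, , drop = FALSE], zs[-1])
      } else 0
    }
    pool <- body_order_pool(5)
    rep <- check_body_order(site_fn, list(position = c(0, 0, 0), z = 29),
                            pool, claimed_order = case$order,
                            tolerance = 1e-9, r_cut = 4.5)
    expect_report_pass(rep)
  }
  # pool atoms outside r_cut are rejected as vacuous
  far_pool <- list(positions = matrix(c(9, 0, 0), 1, 3), z = 29)
  expect_error(check_body_order(function(pos, zs) 0,
                                list(position = c(0, 0, 0), z = 29),
                                far_pool, claimed_order = 2, r_cut = 4.5),
               "vacuous")
})

test_that("generator labels are invariant under rotation and permutation", {
  spec <- toy_spec()
  cf <- labelled_frames(2)[[2]]
  E <- function(cfx) three_body_labels(cfx, spec)$energy
  expect_report_pass(check_equivariance(E, cf, n_rotations = 8, seed = 3,
                                        tolerance = 1e-10))
  expect_report_pass(check_permutation_invariance(E, cf, n_shuffles = 5,
                                                  seed = 4, tolerance = 1e-11))
})

test_that("dimer curves walk the x axis and recover the Morse minimum", {
  grid <- seq(1.6, 4, length.out = 50)
  frames <- dimer_curve(c(1, 29), grid)
  expect_length(frames, 50L)
  for (i in c(1, 25, 50)) {
    expect_equal(frames[[i]]$positions[2, ], c(grid[i], 0, 0))
    expect_equal(frames[[i]]$atomic_numbers, c(1L, 29L))
  }
  spec <- toy_potential_spec("morse", D = 0.5, a = 1.6, r0 = 2.2, r_cut = 30)
  E <- vapply(frames, function(cf) morse_labels(cf, spec)$energy, 1)
  expect_equal(grid[which.min(E)], 2.2, tolerance = 0.06)
})

test_that("make_dataset splits, writes and reproduces byte-for-byte", {
  spec <- toy_spec()
  dir1 <- tempfile("ds"); dir2 <- tempfile("ds")
  ds <- make_dataset(spec, counts = 20, n_atoms = 6, elements = 29,
                     split_fractions = c(0.8, 0.1, 0.1), seed = 12,
                     out_dir = dir1)
  expect_equal(vapply(ds[c("train", "val", "test")], length, 1L),
               c(train = 16L, val = 2L, test = 2L))
  make_dataset(spec, counts = 20, n_atoms = 6, elements = 29,
               split_fractions = c(0.8, 0.1, 0.1), seed = 12, out_dir = dir2)
  for (f in c("train.xyz", "val.xyz", "test.xyz", "manifest.json")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # manifest carries enough to regenerate the dataset
  man <- jsonlite::read_json(file.path(dir1, "manifest.json"),
                             simplifyVector = TRUE)
  spec_re <- toy_potential_spec(man$kind, D = man$parameters$D,
                                a = man$parameters$a, r0 = man$parameters$r0,
                                epsilon = man$parameters$epsilon,
                                r_cut = man$parameters$r_cut,
                                p = man$parameters$p)
  re <- make_dataset(spec_re, counts = man$counts, n_atoms = man$n_atoms,
                     elements = man$elements,
                     split_fractions = man$split_fractions, seed = man$seed,
                     min_separation = man$min_separation)
  expect_equal(re$train[[1]]$positions, ds$train[[1]]$positions)
  expect_equal(re$train[[1]]$energy, ds$train[[1]]$energy)
})
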