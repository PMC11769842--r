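# Verification testbench: executable certificates for equivariance,
# permutation invariance, body order, the symmetrization integral, the
# density trick, locality and cutoff smoothness.

verification_report <- function(name, max_deviation, tolerance, ...) {
  structure(list(name = name, max_deviation = max_deviation,
                 tolerance = tolerance,
                 pass = is.finite(max_deviation) && max_deviation <= tolerance,
                 ...),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  cat(sprintf("[%s] %s: max deviation %.3e (tol %.1e)\n",
              if (x$pass) "PASS" else "FAIL", x$name, x$max_deviation,
              x$tolerance))
  invisible(x)
}

rotate_config <- function(config, Q) {
  atomic_configuration(
    positions = config$positions %*% t(Q),
    atomic_numbers = config$atomic_numbers,
    cell = if (!is.null(config$cell)) config$cell %*% t(Q) else NULL,
    pbc = config$pbc,
    energy = config$energy,
    forces = if (!is.null(config$forces)) config$forces %*% t(Q) else NULL
  )
}

sample_operations <- function(n_rotations, include_reflections, seed) {
  ops <- random_rotations(n_rotations, seed = seed)
  if (include_reflections) {
    refl <- random_rotations(max(1L, n_rotations %/% 5L), seed = seed + 1L)
    ops <- c(ops, lapply(refl, function(R) -R))
  }
  ops
}

#' Certify O(3) equivariance of a configuration-to-feature map
#'
#' Evaluates `max | D(Q) f(x) - f(Q x) |` blockwise over sampled rotations
#' (and reflections).  `fn` may return a feature list keyed by degree
#' (blocks `[n_atoms, n_channels, 2L+1]`), a scalar (checked for invariance)
#' or an `n x 3` matrix (checked to rotate as Euclidean vectors).
#'
#' @param fn function of an [atomic_configuration()].
#' @param configs list of configurations to test on.
#' @param n_rotations rotations per configuration.
#' @param include_reflections add improper operations.
#' @param seed integer seed.
#' @param tolerance pass threshold (default 1e-8).
#' @param relative divide deviations by the feature scale.
#' @return a `verification_report`.
#' @export
check_equivariance <- function(fn, configs, n_rotations = 50L,
                               include_reflections = TRUE, seed = 1L,
                               tolerance = 1e-8, relative = TRUE) {
  if (inherits(configs, "atomic_configuration")) configs <- list(configs)
  ops <- sample_operations(n_rotations, include_reflections, seed)
  dev <- 0
  n_eval <- 0L
  for (cf in configs) {
    ref <- fn(cf)
    for (Q in ops) {
      out <- fn(rotate_config(cf, Q))
      n_eval <- n_eval + 1L
      if (is.list(ref)) {
        for (Lc in names(ref)) {
          L <- as.integer(Lc)
          D <- wigner_D(Q, L)
          expect <- contract_last(ref[[Lc]], t(D))
          scale <- if (relative) max(1, max(abs(ref[[Lc]]))) else 1
          dev <- max(dev, max(abs(out[[Lc]] - expect)) / scale)
        }
      } else if (is.matrix(ref)) {
        expect <- ref %*% t(Q)
        scale <- if (relative) max(1, max(abs(ref))) else 1
        dev <- max(dev, max(abs(out - expect)) / scale)
      } else {
        scale <- if (relative) max(1, abs(ref)) else 1
        dev <- max(dev, max(abs(out - ref)) / scale)
      }
    }
  }
  verification_report("equivariance", dev, tolerance,
                      n_samples = n_eval, seed = seed)
}

#' Certify permutation invariance of a per-atom map
#'
#' Applies random relabelings of the atoms and compares outputs after inverse
#' relabeling.  `fn` must return either a scalar or a per-atom vector/matrix.
#'
#' @param fn function of an [atomic_configuration()].
#' @param config the configuration to test on.
#' @param n_shuffles number of random permutations.
#' @param seed integer seed.
#' @param tolerance default 1e-12.
#' @return a `verification_report`.
#' @export
check_permutation_invariance <- function(fn, config, n_shuffles = 10L,
                                         seed = 1L, tolerance = 1e-12) {
  ref <- fn(config)
  nat <- nrow(config$positions)
  perms <- with_seed(seed, {
    lapply(seq_len(n_shuffles), function(i) sample(nat))
  })
  dev <- 0
  for (p in perms) {
    pc <- atomic_configuration(
      positions = config$positions[p, , drop = FALSE],
      atomic_numbers = config$atomic_numbers[p],
      cell = config$cell, pbc = config$pbc
    )
    out <- fn(pc)
    if (is.matrix(ref)) {
      back <- out
      back[p, ] <- out[seq_len(nat), ]
      dev <- max(dev, max(abs(back - ref)))
    } else if (length(ref) == nat) {
      back <- out
      back[p] <- out
      dev <- max(dev, max(abs(back - ref)))
    } else {
      dev <- max(dev, max(abs(out - ref)))
    }
  }
  verification_report("permutation_invariance", dev, tolerance,
                      n_samples = n_shuffles, seed = seed)
}

#' Certify the body order of a site-energy functional
#'
#' Evaluates the inclusion-exclusion functional
#' `u(S) = sum_{A subset S} (-1)^{|S - A|} E_centre(centre + A)` over neighbour
#' subsets `S`.  A site energy of body order `claimed_order` (counting the
#' central atom) must give `u(S) = 0` for all `|S| >= claimed_order` while
#' some `|S| = claimed_order - 1` stays nonzero.
#'
#' @param site_energy_fn function(positions, atomic_numbers) returning the
#'   energy attributed to the centre atom (always row 1).
#' @param centre list with `position` (3-vector) and `z` (atomic number).
#' @param neighbour_pool list with `positions` (n x 3) and `z` (atomic
#'   numbers); all pool atoms must lie within `r_cut` of the centre.
#' @param claimed_order claimed body order (>= 2).
#' @param tolerance zero threshold for `u` (default 1e-9 eV).
#' @param r_cut used only to validate the pool geometry.
#' @return a `verification_report` with fields `u_by_size` (max |u| per subset
#'   size) and `claimed_order`.
#' @export
check_body_order <- function(site_energy_fn, centre, neighbour_pool,
                             claimed_order, tolerance = 1e-9, r_cut = NULL) {
  pool <- as.matrix(neighbour_pool$positions)
  npool <- nrow(pool)
  stopifnot(claimed_order >= 2, npool >= claimed_order - 1)
  if (!is.null(r_cut)) {
    d <- sqrt(rowSums((pool - matrix(centre$position, npool, 3,
                                     byrow = TRUE))^2))
    if (any(d >= r_cut)) {
      stop("check_body_order: pool atom(s) outside r_cut; test would be vacuous")
    }
  }
  # site energy for every neighbour subset, memoized by bitmask
  evals <- numeric(2^npool)
  for (mask in 0:(2^npool - 1)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, 0:(npool - 1))) > 0)
    pos <- rbind(centre$position, pool[members, , drop = FALSE])
    zs <- c(centre$z, neighbour_pool$z[members])
    evals[mask + 1] <- site_energy_fn(pos, zs)
  }
  # straightforward subset enumeration (pool sizes are small)
  u_max <- stats::setNames(numeric(npool), seq_len(npool))
  for (size in seq_len(npool)) {
    combs <- utils::combn(npool, size, simplify = FALSE)
    for (S in combs) {
      Smask <- sum(bitwShiftL(1L, S - 1L))
      u <- 0
      for (sub_members in c(list(integer(0)),
                            unlist(lapply(seq_along(S), function(k)
                              utils::combn(S, k, simplify = FALSE)),
                              recursive = FALSE))) {
        m <- if (length(sub_members))
          sum(bitwShiftL(1L, sub_members - 1L)) else 0L
        u <- u + (-1)^(size - length(sub_members)) * evals[m + 1]
      }
      u_max[size] <- max(u_max[size], abs(u))
    }
  }
  high <- u_max[as.integer(names(u_max)) >= claimed_order]
  dev <- if (length(high)) max(high) else 0
  rep <- verification_report("body_order", dev, tolerance,
                             claimed_order = claimed_order,
                             u_by_size = u_max)
  # the order below must be realized: some u at size claimed_order - 1 nonzero
  if (claimed_order - 1 <= npool &&
      u_max[claimed_order - 1] <= tolerance) {
    rep$pass <- FALSE
    rep$degenerate <- TRUE
  }
  rep
}

#' Monte-Carlo estimate of the symmetrization integral
#'
#' Estimates `P[m, M] = avg_Q A_m(Q . env) * D^L(Q)[M, M0]` over uniformly
#' sampled O(3) operations.  By the orthogonality of irreducible
#' representations this equals `(1/(2L+1)) sum_eta C[eta, m, LM] B[eta, L M0]`
#' with the orthonormal generalized coupling tensors, so it cross-checks the
#' CG-built symmetrized basis against pure rotation averaging.
#'
#' @param product_basis_fn function(positions) returning the product-basis
#'   value vector over the m multi-index (first factor fastest) for one tuple.
#' @param positions neighbour positions (n x 3) defining the environment.
#' @param degrees degree vector (l_1, ..., l_nu) of the tuple.
#' @param L target degree; `M0` reference column (default M = 0 component).
#' @param n_rotations Monte-Carlo sample size (>= 1000).
#' @param include_reflections average over O(3) rather than SO(3).
#' @param seed integer seed.
#' @param project optional list of coefficient tensors (each of length
#'   `prod(2*degrees+1) * (2L+1)`, e.g. the tensors of
#'   [generalized_coupling()]); for each, the scalar projection of the
#'   integral is estimated with a standard error taken from its own
#'   per-rotation series (so it is exact for that scalar, unaffected by
#'   cross-component correlation).  With the orthonormal coupling tensors the
#'   projection estimates `B[eta, L M0]` directly.
#' @return list with `estimate` and `se` (matrices `[prod(2l+1), 2L+1]`), the
#'   sampled count, and (when `project` is given) `projections`, a data.frame
#'   with columns `estimate` and `se`.
#' @export
brute_force_symmetrize <- function(product_basis_fn, positions, degrees, L,
                                   M0 = L + 1L, n_rotations = 10000L,
                                   include_reflections = TRUE, seed = 1L,
                                   project = NULL) {
  stopifnot(n_rotations >= 1000L)
  positions <- as.matrix(positions)
  rot <- random_rotations(n_rotations, seed = seed)
  if (include_reflections) {
    flip <- rep(c(1, -1), length.out = n_rotations)
    rot <- lapply(seq_len(n_rotations), function(i) flip[i] * rot[[i]])
  }
  dim_m <- prod(2 * degrees + 1)
  sum1 <- matrix(0, dim_m, 2 * L + 1)
  sum2 <- matrix(0, dim_m, 2 * L + 1)
  np <- length(project)
  if (np) {
    Pm <- vapply(project, function(p) as.numeric(p),
                 numeric(dim_m * (2 * L + 1)))
    ps1 <- numeric(np); ps2 <- numeric(np)
  }
  for (Q in rot) {
    Av <- product_basis_fn(positions %*% t(Q))
    DL <- wigner_D(Q, L)
    contrib <- outer(as.numeric(Av), DL[, M0])
    sum1 <- sum1 + contrib
    sum2 <- sum2 + contrib^2
    if (np) {
      s <- as.numeric(crossprod(Pm, as.numeric(contrib)))
      ps1 <- ps1 + s
      ps2 <- ps2 + s^2
    }
  }
  est <- sum1 / n_rotations
  var <- sum2 / n_rotations - est^2
  var[var < 0] <- 0
  se <- sqrt(var / n_rotations)
  out <- list(estimate = est, se = se, n = n_rotations)
  if (np) {
    pe <- ps1 / n_rotations
    pv <- ps2 / n_rotations - pe^2
    pv[pv < 0] <- 0
    out$projections <- data.frame(estimate = pe,
                                  se = sqrt(pv / n_rotations))
  }
  out
}

#' Explicit cluster sum over neighbour tuples
#'
#' The right-hand side of the density-trick identity: for each requested entry
#' tuple, `sum_{j_1..j_nu} prod_xi phi[j_xi, entry_xi, m_xi]` by direct
#' enumeration over *ordered* neighbour tuples (matching the power of a sum).
#'
#' @param edge_basis_values list per entry of matrices
#'   `[n_neighbours, 2l+1]` of one-particle basis values.
#' @param nu correlation order (<= 4; <= 10 neighbours).
#' @param tuples list of entry-id tuples (default: all sorted tuples).
#' @return list per tuple of the m-multi-index value vector (first factor
#'   fastest).
#' @export
explicit_cluster_sum <- function(edge_basis_values, nu, tuples = NULL) {
  nnb <- nrow(edge_basis_values[[1]])
  if (nu > 4 || nnb > 10) {
    stop("explicit_cluster_sum: combinatorial guard exceeded (nu <= 4, <= 10 neighbours)")
  }
  if (is.null(tuples)) {
    tuples <- sorted_tuples(length(edge_basis_values), nu)
  }
  lapply(tuples, function(tp) {
    dims <- vapply(tp, function(q) ncol(edge_basis_values[[q]]), 1L)
    out <- numeric(prod(dims))
    idx_grid <- as.matrix(expand.grid(lapply(seq_len(nu), function(x) 1:nnb)))
    mgrid <- as.matrix(expand.grid(lapply(dims, seq_len)))
    for (row in seq_len(nrow(mgrid))) {
      ms <- mgrid[row, ]
      total <- 0
      for (jrow in seq_len(nrow(idx_grid))) {
        js <- idx_grid[jrow, ]
        prodv <- 1
        for (x in seq_len(nu)) {
          prodv <- prodv * edge_basis_values[[tp[x]]][js[x], ms[x]]
        }
        total <- total + prodv
      }
      out[row] <- total
    }
    out
  })
}

#' Locality / receptive-field certificate
#'
#' Displaces a probe atom and reports the per-atom site-energy changes.  With
#' `T` message-passing layers the receptive field is `T * r_cut`: site
#' energies of atoms farther than `T` hops from the probe (in the union of
#' the before/after graphs) must change by exactly zero.
#'
#' @param model an assembled potential.
#' @param config the configuration.
#' @param probe_atom index of the displaced atom.
#' @param displacement 3-vector (Angstrom).
#' @return a `verification_report` with `delta_E` (per atom), `hops`
#'   (graph distance to the probe) and fields `max_far` / `min_near`.
#' @export
check_locality <- function(model, config, probe_atom, displacement) {
  Tn <- model$config$T
  e_before <- total_energy(model, config)$site_energies
  moved <- config
  moved$positions[probe_atom, ] <- moved$positions[probe_atom, ] + displacement
  e_after <- total_energy(model, moved)$site_energies
  hops_b <- graph_hops(config, model$config$r_cut, probe_atom)
  hops_a <- graph_hops(moved, model$config$r_cut, probe_atom)
  hops <- pmin(hops_b, hops_a)
  dE <- abs(e_after - e_before)
  far <- which(hops > Tn)
  near <- which(hops <= Tn)
  max_far <- if (length(far)) max(dE[far]) else 0
  verification_report("locality", max_far, 0,
                      delta_E = dE, hops = hops,
                      max_far = max_far,
                      min_near = if (length(near)) min(dE[near]) else NA_real_)
}

graph_hops <- function(config, r_cut, source) {
  nl <- build_neighbour_list(config, r_cut)
  nat <- nrow(config$positions)
  adj <- lapply(seq_len(nat), function(i) nl$senders[nl$receivers == i])
  dist <- rep(Inf, nat)
  dist[source] <- 0
  frontier <- source
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[dist[nxt] > d]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Cutoff-smoothness certificate
#'
#' Scans the total energy along a path of configurations crossing the cutoff
#' and reports the largest jump between adjacent samples.
#'
#' @param model an assembled potential.
#' @param path_generator function(s) for `s` in `[0, 1]` returning an
#'   [atomic_configuration()].
#' @param n_steps number of samples along the path.
#' @param tolerance maximum admissible jump (default 1e-8 eV).
#' @return a `verification_report` with the energy trace.
#' @export
check_cutoff_smoothness <- function(model, path_generator, n_steps = 100L,
                                    tolerance = 1e-8) {
  s <- seq(0, 1, length.out = n_steps)
  E <- vapply(s, function(si) total_energy(model, path_generator(si))$energy, 1)
  jumps <- abs(diff(E))
  verification_report("cutoff_smoothness", max(jumps), tolerance,
                      energies = E, s = s)
}

#' Direct linear-ACE site energies without the density trick
#'
#' Independent evaluation of a delta-mode (linear ACE) model: for every atom
#' the symmetrized basis is computed from explicit sums over ordered
#' neighbour tuples ([explicit_cluster_sum()]) contracted with the
#' generalized coupling tensors, bypassing `product_basis` entirely.
#'
#' @param model a delta-embedding (linear ACE) model.
#' @param config an [atomic_configuration()].
#' @return per-atom site energies (eV).
#' @export
direct_ace_energy <- function(model, config) {
  cfg <- model$config
  stopifnot(cfg$embedding == "delta")
  attrs <- one_hot_attributes(config$atomic_numbers, cfg$elements)
  nl <- build_neighbour_list(config, cfg$r_cut)
  rc <- model_radial_config(cfg, 1L)
  basis <- model$params$basis
  entries <- basis$entries
  lam <- max(cfg$lambda, 1)
  nat <- nrow(config$positions)
  site <- numeric(nat)
  for (i in seq_len(nat)) {
    sel <- which(nl$receivers == i)
    zi <- attrs$indices[i]
    w <- model$params$ace_weights[[zi]]
    acc <- 0
    col <- 0L
    if (length(sel)) {
      disp <- nl$displacements[sel, , drop = FALSE]
      r <- nl$distances[sel]
      Rb <- enveloped_bessel(r, rc)
      Y <- sh_matrix(disp / r, cfg$l_max)
      zj <- attrs$indices[nl$senders[sel]]
      phi <- lapply(seq_len(nrow(entries)), function(q) {
        n <- entries$n[q]; z <- entries$z[q]; l <- entries$l[q]
        (Rb[, n] * (zj == z) / lam) * Y[, sh_cols(l), drop = FALSE]
      })
    }
    for (tp in basis$tuples) {
      degs <- entries$l[tp]
      gc <- generalized_coupling(degs, 0L)
      if (!length(gc$tensors)) next
      if (length(sel)) {
        cs <- explicit_cluster_sum(phi, length(tp), tuples = list(tp))[[1]]
      } else {
        cs <- numeric(prod(2 * degs + 1))
      }
      for (e in seq_along(gc$tensors)) {
        col <- col + 1L
        acc <- acc + w[col] * sum(cs * as.numeric(gc$tensors[[e]]))
      }
    }
    site[i] <- acc + model$params$e0[zi]
  }
  site
}
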