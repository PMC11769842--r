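# Synthetic datasets: random configurations labelled with analytic
# body-ordered toy potentials (Morse pairs, plus an explicit three-body
# angular term) with exact analytic forces, dimer curves, and dataset
# splitting/writing.  These potentials have exact body order 2 and 3, giving
# the body-order machinery a nontrivial certified target.

#' Toy-potential specification
#'
#' Pairwise Morse well `V2(r) = (D (1 - exp(-a (r - r0)))^2 - D) * f_env(r)`
#' plus, for `kind = "morse_plus_three_body"`, the strictly three-body term
#' `V3 = sum_i sum_{j<k in N(i)} eps * cos^2(theta_jik) g(r_ij) g(r_ik)` with
#' smooth envelopes `f_env = g = ` [polynomial_cutoff()].
#'
#' @param kind `"morse"` or `"morse_plus_three_body"`.
#' @param D well depth (eV); @param a inverse width (1/Angstrom);
#' @param r0 equilibrium distance (Angstrom); may each be a scalar or an
#'   `n_elements x n_elements` symmetric matrix for per-pair parameters.
#' @param epsilon three-body strength (eV).
#' @param r_cut envelope cutoff (Angstrom); @param p envelope power.
#' @param elements atomic numbers indexing per-pair parameter matrices.
#' @return object of class `toy_potential_spec`.
#' @export
toy_potential_spec <- function(kind = c("morse", "morse_plus_three_body"),
                               D = 0.5, a = 1.6, r0 = 2.2, epsilon = 0.15,
                               r_cut = 5, p = 6L, elements = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(D > 0), all(a > 0), all(r0 > 0), r_cut > 0)
  structure(list(kind = kind, D = D, a = a, r0 = r0, epsilon = epsilon,
                 r_cut = r_cut, p = as.integer(p), elements = elements),
            class = "toy_potential_spec")
}

pair_param <- function(par, zi, zj, elements) {
  if (is.matrix(par)) {
    i <- match(zi, elements); j <- match(zj, elements)
    par[cbind(i, j)]
  } else {
    rep(par, length(zi))
  }
}

cutoff_value <- function(r, r_cut, p) {
  u <- r / r_cut
  inside <- r < r_cut
  A <- (p + 1) * (p + 2) / 2; B <- p * (p + 2); C <- p * (p + 1) / 2
  (1 - A * u^p + B * u^(p + 1) - C * u^(p + 2)) * inside
}

cutoff_deriv <- function(r, r_cut, p) {
  u <- r / r_cut
  inside <- r < r_cut
  A <- (p + 1) * (p + 2) / 2; B <- p * (p + 2); C <- p * (p + 1) / 2
  ((-A * p * u^(p - 1) + B * (p + 1) * u^p - C * (p + 2) * u^(p + 1)) /
     r_cut) * inside
}

#' Morse pair energy and analytic forces
#'
#' @param config an [atomic_configuration()].
#' @param spec a [toy_potential_spec()] (the pair part is used).
#' @return list with `energy` (eV) and `forces` (`n x 3`, eV/Angstrom).
#' @export
morse_labels <- function(config, spec) {
  nl <- build_neighbour_list(config, spec$r_cut)
  nat <- nrow(config$positions)
  F <- matrix(0, nat, 3)
  if (!length(nl$distances)) return(list(energy = 0, forces = F))
  if (min(nl$distances) < 1e-6) stop("morse_labels: overlapping atoms")
  zi <- config$atomic_numbers[nl$receivers]
  zj <- config$atomic_numbers[nl$senders]
  D <- pair_param(spec$D, zi, zj, spec$elements)
  a <- pair_param(spec$a, zi, zj, spec$elements)
  r0 <- pair_param(spec$r0, zi, zj, spec$elements)
  r <- nl$distances
  ex <- exp(-a * (r - r0))
  V <- D * (1 - ex)^2 - D
  dV <- 2 * D * a * (1 - ex) * ex
  f <- cutoff_value(r, spec$r_cut, spec$p)
  df <- cutoff_deriv(r, spec$r_cut, spec$p)
  # each unordered pair appears as two directed edges
  E <- sum(V * f) / 2
  dE <- (dV * f + V * df) / 2
  unit <- nl$displacements / r
  # r_e depends on r_sender with +unit and on r_receiver with -unit; F = -dE/dr
  for (d in 1:3) {
    contrib <- dE * unit[, d]
    F[, d] <- F[, d] - tapply_sum(contrib, nl$senders, nat) +
      tapply_sum(contrib, nl$receivers, nat)
  }
  list(energy = E, forces = F)
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Morse plus explicit three-body energy and analytic forces
#'
#' Adds `sum_{j<k in N(i)} eps cos^2(theta_jik) g(r_ij) g(r_ik)` to the Morse
#' pair part; the added term is strictly three-body (center + 2 neighbours).
#'
#' @inheritParams morse_labels
#' @return list with `energy` and `forces`.
#' @export
three_body_labels <- function(config, spec) {
  if (spec$kind != "morse_plus_three_body") {
    stop("three_body_labels: spec kind must be morse_plus_three_body")
  }
  base <- morse_labels(config, spec)
  nl <- build_neighbour_list(config, spec$r_cut)
  nat <- nrow(config$positions)
  E3 <- 0
  F3 <- matrix(0, nat, 3)
  eps <- spec$epsilon
  for (i in seq_len(nat)) {
    sel <- which(nl$receivers == i)
    if (length(sel) < 2) next
    disp <- nl$displacements[sel, , drop = FALSE]
    r <- nl$distances[sel]
    g <- cutoff_value(r, spec$r_cut, spec$p)
    dg <- cutoff_deriv(r, spec$r_cut, spec$p)
    jat <- nl$senders[sel]
    nn <- length(sel)
    for (aa in 1:(nn - 1)) {
      for (bb in (aa + 1):nn) {
        dj <- disp[aa, ]; dk <- disp[bb, ]
        rj <- r[aa]; rk <- r[bb]
        cth <- sum(dj * dk) / (rj * rk)
        E3 <- E3 + eps * cth^2 * g[aa] * g[bb]
        # gradients of cos(theta) w.r.t. the two displacement vectors
        dc_dj <- dk / (rj * rk) - cth * dj / rj^2
        dc_dk <- dj / (rj * rk) - cth * dk / rk^2
        gj <- eps * (2 * cth * dc_dj * g[aa] * g[bb] +
                       cth^2 * dg[aa] * (dj / rj) * g[bb])
        gk <- eps * (2 * cth * dc_dk * g[aa] * g[bb] +
                       cth^2 * g[aa] * dg[bb] * (dk / rk))
        # d_j = r_j - r_i: force on j is -gj, on k is -gk, centre gets both
        F3[jat[aa], ] <- F3[jat[aa], ] - gj
        F3[jat[bb], ] <- F3[jat[bb], ] - gk
        F3[i, ] <- F3[i, ] + gj + gk
      }
    }
  }
  list(energy = base$energy + E3, forces = base$forces + F3)
}

#' Label a configuration with a toy potential
#'
#' @inheritParams morse_labels
#' @return the configuration with `energy` and `forces` fields set.
#' @export
label_config <- function(config, spec) {
  lab <- if (spec$kind == "morse") morse_labels(config, spec)
    else three_body_labels(config, spec)
  config$energy <- lab$energy
  config$forces <- lab$forces
  config
}

#' Random atomic configurations
#'
#' Seeded rejection sampling with a minimum pair separation; `cluster` mode
#' samples positions in a ball, `box` mode in a periodic cubic cell.
#'
#' @param n_configs number of frames.
#' @param n_atoms atoms per frame.
#' @param elements atomic numbers to draw from (uniformly).
#' @param mode `"cluster"` or `"box"`.
#' @param min_separation smallest admissible pair distance (Angstrom).
#' @param radius cluster-ball radius; default scales with `n_atoms`.
#' @param box_length periodic cell edge; default scales with `n_atoms`.
#' @param seed integer seed; the same seed reproduces the list bit for bit.
#' @param max_tries rejection-sampling bound per frame.
#' @return list of [atomic_configuration()].
#' @export
random_configurations <- function(n_configs, n_atoms, elements = 29,
                                  mode = c("cluster", "box"),
                                  min_separation = 1.8, radius = NULL,
                                  box_length = NULL, seed = 1L,
                                  max_tries = 200L) {
  mode <- match.arg(mode)
  stopifnot(min_separation > 0, n_atoms >= 1)
  if (is.null(radius)) radius <- 0.9 * min_separation * n_atoms^(1 / 3) + 1
  if (is.null(box_length)) box_length <- 1.3 * min_separation * n_atoms^(1 / 3)
  with_seed(seed, {
    lapply(seq_len(n_configs), function(fr) {
      for (attempt in seq_len(max_tries)) {
        if (mode == "cluster") {
          pos <- matrix(0, n_atoms, 3)
          placed <- 0L
          ok <- TRUE
          while (placed < n_atoms) {
            got <- FALSE
            for (tr in seq_len(max_tries)) {
              cand <- stats::runif(3, -radius, radius)
              if (sum(cand^2) > radius^2) next
              if (placed == 0L) { got <- TRUE; break }
              d2 <- colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2)
              if (min(d2) >= min_separation^2) { got <- TRUE; break }
            }
            if (!got) { ok <- FALSE; break }
            placed <- placed + 1L
            pos[placed, ] <- cand
          }
          if (!ok) next
          cell <- NULL; pbc <- NULL
        } else {
          # sequential placement with minimum-image rejection
          pos <- matrix(0, n_atoms, 3)
          placed <- 0L
          ok <- TRUE
          while (placed < n_atoms) {
            got <- FALSE
            for (tr in seq_len(max_tries)) {
              cand <- stats::runif(3, 0, box_length)
              if (placed == 0L) { got <- TRUE; break }
              delta <- pos[seq_len(placed), , drop = FALSE] -
                matrix(cand, placed, 3, byrow = TRUE)
              delta <- delta - box_length * round(delta / box_length)
              if (min(rowSums(delta^2)) >= min_separation^2) {
                got <- TRUE; break
              }
            }
            if (!got) { ok <- FALSE; break }
            placed <- placed + 1L
            pos[placed, ] <- cand
          }
          if (!ok) next
          cell <- diag(box_length, 3); pbc <- c(TRUE, TRUE, TRUE)
        }
        zs <- if (length(elements) == 1L) rep(elements, n_atoms) else
          sample(elements, n_atoms, replace = TRUE)
        return(atomic_configuration(pos, zs, cell, pbc))
      }
      stop("random_configurations: could not satisfy min_separation (frame ",
           fr, ")")
    })
  })
}

#' Dimer configurations along a distance grid
#'
#' @param element_pair two atomic numbers.
#' @param r_grid positive ascending distances (Angstrom).
#' @return list of two-atom configurations on the x axis, one per distance.
#' @export
dimer_curve <- function(element_pair, r_grid) {
  stopifnot(all(r_grid > 0), !is.unsorted(r_grid))
  lapply(r_grid, function(r) {
    atomic_configuration(rbind(c(0, 0, 0), c(r, 0, 0)),
                         as.integer(element_pair))
  })
}

#' Generate, label, split and write a synthetic dataset
#'
#' @param spec a [toy_potential_spec()].
#' @param counts total number of frames.
#' @param n_atoms atoms per frame.
#' @param elements atomic numbers.
#' @param split_fractions train/val/test fractions summing to 1.
#' @param seed integer seed.
#' @param out_dir output directory (created if needed); extended-XYZ files
#'   `train.xyz`, `val.xyz`, `test.xyz` plus `manifest.json`.
#' @param min_separation passed to [random_configurations()].
#' @return list with the three split lists and the manifest (invisibly when
#'   written).
#' @export
make_dataset <- function(spec, counts, n_atoms = 8L, elements = 29,
                         split_fractions = c(0.8, 0.1, 0.1), seed = 1L,
                         out_dir = NULL, min_separation = 1.8) {
  stopifnot(abs(sum(split_fractions) - 1) < 1e-12)
  configs <- random_configurations(counts, n_atoms, elements,
                                   min_separation = min_separation,
                                   seed = seed)
  configs <- lapply(configs, label_config, spec = spec)
  n_train <- round(split_fractions[1] * counts)
  n_val <- round(split_fractions[2] * counts)
  idx <- seq_len(counts)
  splits <- list(train = configs[idx <= n_train],
                 val = configs[idx > n_train & idx <= n_train + n_val],
                 test = configs[idx > n_train + n_val])
  manifest <- list(kind = spec$kind,
                   parameters = list(D = spec$D, a = spec$a, r0 = spec$r0,
                                     epsilon = spec$epsilon,
                                     r_cut = spec$r_cut, p = spec$p),
                   counts = counts, n_atoms = n_atoms, elements = elements,
                   split_fractions = split_fractions, seed = seed,
                   min_separation = min_separation,
                   sizes = vapply(splits, length, 1L))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_extxyz(splits$train, file.path(out_dir, "train.xyz"))
    write_extxyz(splits$val, file.path(out_dir, "val.xyz"))
    write_extxyz(splits$test, file.path(out_dir, "test.xyz"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  c(splits, list(manifest = manifest))
}
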