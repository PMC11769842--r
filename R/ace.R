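# One layer of equivariant ACE: one-particle basis on edges, density-trick
# pooling to the atomic (A) basis, the product basis, generalized-CG
# symmetrization to the B basis, and weighted message formation; plus the
# direct nu = 1 convolution.
#
# Feature blocks are stored as lists keyed by the string of their degree L,
# each an array [n_atoms, n_channels, 2L+1]; all blocks carry the natural
# spherical-harmonic parity (-1)^L.  Every aggregation is a plain (complex-
# safe) matrix product in the canonical edge order, so results are
# bit-reproducible and permutation invariant.

feature_block_names <- function(h) as.integer(names(h))

#' Irreducible-representation layout of a feature set
#'
#' @param h feature list (arrays `[n_atoms, n_channels, 2L+1]` keyed by degree).
#' @return data.frame with columns `mul`, `L`, `parity` (blocks in ascending
#'   `L`) and attribute `total_dim`.
#' @export
irrep_spec <- function(h) {
  Ls <- sort(feature_block_names(h))
  df <- data.frame(
    mul = vapply(Ls, function(L) dim(h[[as.character(L)]])[2], 1L),
    L = Ls,
    parity = as.integer((-1)^Ls)
  )
  attr(df, "total_dim") <- sum(df$mul * (2 * df$L + 1))
  df
}

#' Initial scalar embedding of the chemical elements
#'
#' `h0[i, k] = sum_z weights[z, k] * one_hot[i, z]`; with identity weights
#' (delta mode) the initial features are the one-hot attributes themselves.
#'
#' @param attributes a [one_hot_attributes()] object.
#' @param weights `n_elements x n_channels` matrix.
#' @return feature list with a single degree-0 block
#'   `[n_atoms, n_channels, 1]`.
#' @export
initial_embedding <- function(attributes, weights) {
  oh <- attributes$one_hot
  if (ncol(oh) != nrow(weights)) {
    stop("initial_embedding: weights must be [n_elements x n_channels]")
  }
  h0 <- oh %*% weights
  list("0" = array(h0, c(nrow(h0), ncol(h0), 1L)))
}

# Admissible (l1, l2, L) paths: triangle rule plus even total degree so the
# output block keeps natural parity.
layer_paths <- function(l_max, sender_Ls, L_max) {
  out <- expand.grid(l1 = 0:l_max, l2 = sender_Ls, L = 0:L_max)
  keep <- with(out, L >= abs(l1 - l2) & L <= l1 + l2 & (l1 + l2 + L) %% 2 == 0)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$L, out$l1, out$l2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-particle basis on the edges of the neighbourhood graph
#'
#' In embedded mode each basis entry is one admissible `(l1, l2 -> lambda)`
#' path: the per-path radial value times the Clebsch-Gordan-coupled product of
#' the degree-`l1` spherical harmonic of the edge direction and the sender's
#' degree-`l2` feature block.  In delta mode entries are `(n, z_sender, l)`
#' combinations: fixed orthogonal radials times a sender-element indicator
#' times the spherical harmonic, recovering the discrete one-particle basis.
#'
#' @param t layer index (0-based; informational).
#' @param neighbour_list a [build_neighbour_list()] result.
#' @param node_states list with `h` (feature list) and `attrs`
#'   (a [one_hot_attributes()]).
#' @param radial_values embedded mode: array `[n_edges, n_channels, n_paths]`
#'   aligned with the path table; delta mode: matrix `[n_edges, n_basis]` of
#'   enveloped radials.
#' @param config list with `l_max`, `L_max`, `mode` ("embedded" or "delta").
#' @return object of class `edge_basis`: `entries` (data.frame with a degree
#'   column `l`), `values` (list of arrays `[n_edges, n_channels, 2l+1]`),
#'   `paths` (embedded mode path table).
#' @export
one_particle_basis <- function(t, neighbour_list, node_states, radial_values,
                               config) {
  nl <- neighbour_list
  ne <- length(nl$receivers)
  disp <- nl$displacements
  r <- nl$distances
  unit <- disp / r
  h <- node_states$h
  mode <- config$mode %||% "embedded"
  if (mode == "embedded") {
    sender_Ls <- sort(feature_block_names(h))
    paths <- layer_paths(config$l_max, sender_Ls, config$L_max)
    Y <- sh_matrix(unit, max(config$l_max, 1L))
    values <- vector("list", nrow(paths))
    for (p in seq_len(nrow(paths))) {
      l1 <- paths$l1[p]; l2 <- paths$l2[p]; L <- paths$L[p]
      hs <- h[[as.character(l2)]][nl$senders, , , drop = FALSE]
      nch <- dim(hs)[2]
      C <- cg_real_ortho(l1, l2, L)
      acc <- array(hs[1] * 0, c(ne, nch, 2 * L + 1))
      for (m1 in seq_len(2 * l1 + 1)) {
        Cm <- matrix(C[m1, , ], 2 * l2 + 1, 2 * L + 1)
        if (all(Cm == 0)) next
        acc <- acc + as.vector(Y[, l1^2 + m1]) * contract_last(hs, Cm)
      }
      values[[p]] <- acc * as.vector(radial_values[, , p])
    }
    entries <- data.frame(l = paths$L)
    structure(list(entries = entries, values = values, paths = paths,
                   t = t, mode = mode, n_edges = ne),
              class = "edge_basis")
  } else {
    # delta mode: discrete element labels, fixed orthogonal radial basis
    attrs <- node_states$attrs
    zj <- attrs$indices[nl$senders]
    n_elem <- length(attrs$element_table)
    n_basis <- ncol(radial_values)
    Y <- sh_matrix(unit, config$l_max)
    grid <- expand.grid(n = seq_len(n_basis), z = seq_len(n_elem),
                        l = 0:config$l_max)
    values <- vector("list", nrow(grid))
    for (q in seq_len(nrow(grid))) {
      n <- grid$n[q]; z <- grid$z[q]; l <- grid$l[q]
      sel <- as.numeric(zj == z)
      base <- radial_values[, n] * sel
      values[[q]] <- array(base * Y[, sh_cols(l), drop = FALSE],
                           c(ne, 1L, 2 * l + 1))
    }
    entries <- data.frame(n = grid$n, z = grid$z, l = grid$l)
    structure(list(entries = entries, values = values, paths = NULL,
                   t = t, mode = mode, n_edges = ne),
              class = "edge_basis")
  }
}

#' Pool the one-particle basis into the atomic (A) basis
#'
#' The density trick's first half: `A[i, k, v] = (1/lambda) * sum_{j in N(i)}
#' phi[k, v](i, j)`, summed in the canonical edge order.  An atom with no
#' neighbours gets exactly zero.
#'
#' @param edge_basis an [one_particle_basis()] result.
#' @param receivers receiver atom index per edge (1-based).
#' @param lambda positive normalization constant (e.g. average neighbour
#'   count).
#' @param n_atoms number of atoms.
#' @return object of class `atomic_basis` mirroring `edge_basis` with
#'   per-atom arrays `[n_atoms, n_channels, 2l+1]`.
#' @export
pool_atomic_basis <- function(edge_basis, receivers, lambda, n_atoms) {
  stopifnot(lambda > 0)
  P <- pooling_matrix(receivers, n_atoms)
  values <- lapply(edge_basis$values, function(v) {
    d <- dim(v)
    pooled <- P %*% matrix(v, d[1], d[2] * d[3])
    array(pooled / lambda, c(n_atoms, d[2], d[3]))
  })
  structure(list(entries = edge_basis$entries, values = values,
                 paths = edge_basis$paths, lambda = lambda,
                 mode = edge_basis$mode, n_atoms = n_atoms),
            class = "atomic_basis")
}

# Enumerate sorted index tuples (with repetition) of entry ids.
sorted_tuples <- function(n_entries, nu) {
  if (nu == 1) return(lapply(seq_len(n_entries), function(i) i))
  out <- list()
  recurse <- function(prefix, start) {
    if (length(prefix) == nu) {
      out[[length(out) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (i in start:n_entries) recurse(c(prefix, i), i)
  }
  recurse(integer(0), 1L)
  out
}

#' Product basis of correlation order nu
#'
#' `PA[i, k, v] = prod_xi A[i, k, v_xi]` over sorted entry tuples; the
#' uncoupled channel index `k` never enters the products.  The `nu = 1` slice
#' is the A basis itself.
#'
#' @param atomic_basis a [pool_atomic_basis()] result.
#' @param nu correlation order, >= 1.
#' @param tuple_index_set optional list of sorted entry-id tuples; by default
#'   all sorted `nu`-tuples that can couple to at least one degree
#'   `L <= max_L` are used (triangle-rule prefilter).
#' @param max_L degree bound for the prefilter (default: max entry degree).
#' @param max_degree_sum optional bound on `sum(n_xi + l_xi)` applied in delta
#'   mode (full-coupling polynomial-degree truncation).
#' @return object of class `product_basis`: `tuples`, `degrees` (list of
#'   degree vectors) and `values` (arrays `[n_atoms, n_channels, prod(2l+1)]`
#'   with m-indices of the first factor varying fastest).
#' @export
product_basis <- function(atomic_basis, nu, tuple_index_set = NULL,
                          max_L = NULL, max_degree_sum = NULL) {
  if (nu < 1) stop("product_basis: nu must be >= 1")
  A <- atomic_basis
  degrees_all <- A$entries$l
  if (is.null(max_L)) max_L <- max(degrees_all)
  if (is.null(tuple_index_set)) {
    tuple_index_set <- sorted_tuples(length(A$values), nu)
    keep <- vapply(tuple_index_set, function(tp) {
      degs <- degrees_all[tp]
      if (!is.null(max_degree_sum) && !is.null(A$entries$n)) {
        if (sum(A$entries$n[tp] + degs) > max_degree_sum) return(FALSE)
      }
      any(vapply(0:max_L, function(L) {
        length(coupling_schemes(degs, L)) > 0
      }, TRUE))
    }, TRUE)
    tuple_index_set <- tuple_index_set[keep]
  }
  values <- lapply(tuple_index_set, function(tp) {
    v <- A$values[[tp[1]]]
    if (length(tp) > 1) {
      for (x in tp[-1]) {
        d1 <- dim(v); d2 <- dim(A$values[[x]])
        # outer product over the m indices, first factor fastest
        vv <- array(0 * v[1], c(d1[1], d1[2], d1[3] * d2[3]))
        for (m2 in seq_len(d2[3])) {
          cols <- ((m2 - 1) * d1[3] + 1):(m2 * d1[3])
          vv[, , cols] <- v * as.vector(A$values[[x]][, , m2])
        }
        v <- vv
      }
    }
    v
  })
  structure(list(tuples = tuple_index_set,
                 degrees = lapply(tuple_index_set, function(tp) degrees_all[tp]),
                 values = values, entries = A$entries, nu = nu,
                 mode = A$mode, n_atoms = A$n_atoms),
            class = "product_basis")
}

#' Symmetrize the product basis to definite O(3) behaviour
#'
#' `B[i, k, eta, L, M] = sum_v C[eta, v, LM] * PA[i, k, v]` using the
#' generalized coupling coefficients of each tuple's degree vector.
#'
#' @param product_basis a [product_basis()] result.
#' @param L target degree.
#' @param coupling optional list of [generalized_coupling()] objects, one per
#'   tuple (computed from each tuple's degrees by default).
#' @return object of class `symmetrized_basis`: data.frame `index` with
#'   columns `tuple` and `eta`, and `values`, a list of arrays
#'   `[n_atoms, n_channels, 2L+1]`.
#' @export
symmetrize <- function(product_basis, L, coupling = NULL) {
  PB <- product_basis
  if (is.null(coupling)) {
    coupling <- lapply(PB$degrees, function(d) generalized_coupling(d, L))
  }
  idx_tuple <- integer(0); idx_eta <- integer(0)
  values <- list()
  for (ti in seq_along(PB$tuples)) {
    cc <- coupling[[ti]]
    if (!identical(as.integer(cc$degrees), as.integer(PB$degrees[[ti]]))) {
      stop("symmetrize: coupling degrees do not match tuple degrees")
    }
    if (!length(cc$tensors)) next
    v <- PB$values[[ti]]
    d <- dim(v)
    vm <- matrix(v, d[1] * d[2], d[3])
    for (e in seq_along(cc$tensors)) {
      Cm <- matrix(cc$tensors[[e]], d[3], 2 * L + 1)
      bv <- vm %*% Cm
      values[[length(values) + 1]] <- array(bv, c(d[1], d[2], 2 * L + 1))
      idx_tuple <- c(idx_tuple, ti)
      idx_eta <- c(idx_eta, e)
    }
  }
  structure(list(index = data.frame(tuple = idx_tuple, eta = idx_eta),
                 values = values, L = L, nu = PB$nu, mode = PB$mode,
                 n_atoms = PB$n_atoms),
            class = "symmetrized_basis")
}

#' Form the per-atom message from the symmetrized basis
#'
#' `m[i, k, L, M] = sum_eta w[k, eta, L](z_i) * B[i, k, eta, L, M]`, with the
#' per-atom weight dependence realized through the central atom's element.
#'
#' @param symmetrized_basis a [symmetrize()] result.
#' @param weights either a matrix `[n_channels, n_basis_functions]` (shared
#'   across elements) or a list of such matrices keyed by element-table index.
#'   A single row vector is recycled across channels.
#' @param attrs a [one_hot_attributes()] (required for per-element weights).
#' @return array `[n_atoms, n_channels, 2L+1]`.
#' @export
form_message <- function(symmetrized_basis, weights, attrs = NULL) {
  B <- symmetrized_basis
  nb <- length(B$values)
  if (nb == 0) {
    stop("form_message: empty symmetrized basis")
  }
  d <- dim(B$values[[1]])
  out <- array(B$values[[1]][1] * 0, d)
  per_element <- is.list(weights) && !is.matrix(weights)
  if (per_element && is.null(attrs)) {
    stop("form_message: per-element weights need node attributes")
  }
  expand_w <- function(w) {
    if (is.null(dim(w))) matrix(rep(w, each = d[2]), d[2], nb) else w
  }
  if (!per_element) {
    W <- expand_w(weights)
    for (b in seq_len(nb)) {
      out <- out + rep(W[, b], each = d[1]) * B$values[[b]]
    }
  } else {
    for (z in unique(attrs$indices)) {
      rows <- which(attrs$indices == z)
      W <- expand_w(weights[[z]])
      for (b in seq_len(nb)) {
        out[rows, , ] <- out[rows, , , drop = FALSE] +
          rep(W[, b], each = length(rows)) *
          B$values[[b]][rows, , , drop = FALSE]
      }
    }
  }
  out
}

#' Direct nu = 1 equivariant convolution
#'
#' The ordinary-Clebsch-Gordan simplification of the ACE message at
#' correlation order 1:
#' `m[i, k, L, M] = sum_{l1 l2} C^{LM}_{l1 m1, l2 m2} sum_j R[k, l1 l2 L](r_ji)
#'  Y[l1 m1](r_ji) h[j, k, l2 m2] / lambda`.
#' This is an independent code path from the generic
#' product/symmetrize engine and is used as its cross-check at nu = 1.
#'
#' @param neighbour_list a [build_neighbour_list()] result.
#' @param node_states list with feature list `h`.
#' @param radial_values array `[n_edges, n_channels, n_paths]` aligned with
#'   `layer_paths(l_max, sender degrees, L_max)`.
#' @param l_max,L_max angular truncations.
#' @param lambda pooling normalization, > 0.
#' @return feature list keyed by degree with arrays
#'   `[n_atoms, n_channels, 2L+1]`.
#' @export
nequip_convolution <- function(neighbour_list, node_states, radial_values,
                               l_max, L_max, lambda = 1) {
  nl <- neighbour_list
  h <- node_states$h
  nat <- nl$n_atoms
  ne <- length(nl$receivers)
  sender_Ls <- sort(feature_block_names(h))
  paths <- layer_paths(l_max, sender_Ls, L_max)
  unit <- nl$displacements / nl$distances
  Y <- sh_matrix(unit, max(l_max, 1L))
  P <- pooling_matrix(nl$receivers, nat)
  nch <- dim(h[[1]])[2]
  out <- list()
  for (L in 0:L_max) {
    sel <- which(paths$L == L)
    if (!length(sel)) next
    acc <- NULL
    for (p in sel) {
      l1 <- paths$l1[p]; l2 <- paths$l2[p]
      hs <- h[[as.character(l2)]][nl$senders, , , drop = FALSE]
      C <- cg_real_ortho(l1, l2, L)
      phi <- array(hs[1] * 0, c(ne, nch, 2 * L + 1))
      for (m1 in seq_len(2 * l1 + 1)) {
        Cm <- matrix(C[m1, , ], 2 * l2 + 1, 2 * L + 1)
        if (all(Cm == 0)) next
        phi <- phi + as.vector(Y[, l1^2 + m1]) * contract_last(hs, Cm)
      }
      phi <- phi * as.vector(radial_values[, , p])
      pooled <- P %*% matrix(phi, ne, nch * (2 * L + 1))
      pooled <- array(pooled, c(nat, nch, 2 * L + 1))
      acc <- if (is.null(acc)) pooled else acc + pooled
    }
    out[[as.character(L)]] <- acc / lambda
  }
  out
}
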