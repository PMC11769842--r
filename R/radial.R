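# Radial features: Bessel basis, smooth polynomial cutoff envelope, and the
# learnable radial variants (element-agnostic MLP; element-dependent linear).
# All evaluators are complex-safe so position derivatives can be taken by
# complex-step differentiation.

#' Radial configuration
#'
#' @param r_cut cutoff radius in Angstrom, > 0.
#' @param n_basis number of Bessel functions, >= 1.
#' @param p cutoff envelope power, >= 1.
#' @param mode one of `"fixed-orthogonal"`, `"agnostic-mlp"`,
#'   `"element-dependent"`.
#' @param mlp_widths hidden-layer widths of the agnostic MLP.
#' @param n_paths number of (l1, l2, L) combinations served.
#' @param envelope `"polynomial"` (smooth, default) or `"hard"` (step function;
#'   only used by the verification testbench to demonstrate cutoff-smoothness
#'   failures).
#' @return list of class `radial_config`.
#' @export
radial_config <- function(r_cut, n_basis = 8L, p = 6L,
                          mode = c("fixed-orthogonal", "agnostic-mlp",
                                   "element-dependent"),
                          mlp_widths = c(64L, 64L, 64L), n_paths = 1L,
                          envelope = c("polynomial", "hard")) {
  mode <- match.arg(mode)
  envelope <- match.arg(envelope)
  stopifnot(r_cut > 0, n_basis >= 1, p >= 1, n_paths >= 1)
  structure(list(r_cut = r_cut, n_basis = as.integer(n_basis),
                 p = as.integer(p), mode = mode,
                 mlp_widths = as.integer(mlp_widths),
                 n_paths = as.integer(n_paths), envelope = envelope),
            class = "radial_config")
}

#' Bessel radial basis
#'
#' `R_n(r) = sqrt(2 / r_cut) * sin(n pi r / r_cut) / r` for `n = 1..n_basis`.
#' The cutoff envelope is *not* applied here; values beyond `r_cut` may be
#' nonzero.  `r * R_n(r)` are orthonormal on `(0, r_cut)`.
#'
#' @param r distances (Angstrom), > 0; may be a vector.
#' @param config a [radial_config()].
#' @return matrix `[length(r), n_basis]`.
#' @export
bessel_basis <- function(r, config) {
  if (any(Re(r) <= 0)) stop("bessel_basis: distances must be > 0")
  n <- seq_len(config$n_basis)
  arg <- outer(r, n * pi / config$r_cut)
  sqrt(2 / config$r_cut) * sin(arg) / r
}

#' Smooth polynomial cutoff envelope
#'
#' With `u = r / r_cut` and envelope power `p`:
#' `f(u) = 1 - (p+1)(p+2)/2 u^p + p(p+2) u^(p+1) - p(p+1)/2 u^(p+2)` for
#' `u < 1` and 0 beyond; `f`, `f'` and `f''` all vanish at `r_cut`, and
#' `f(0) = 1`.
#'
#' @param r distances >= 0 (vectorized).
#' @param config a [radial_config()]; `config$envelope = "hard"` replaces the
#'   smooth form by a step function (testbench mutation only).
#' @return values in `[0, 1]`, same length as `r`.
#' @export
polynomial_cutoff <- function(r, config) {
  u <- r / config$r_cut
  inside <- Re(u) < 1
  if (config$envelope == "hard") {
    return(as.numeric(inside) + 0 * u)
  }
  p <- config$p
  f <- 1 - (p + 1) * (p + 2) / 2 * u^p + p * (p + 2) * u^(p + 1) -
    p * (p + 1) / 2 * u^(p + 2)
  f * inside
}

# Enveloped Bessel features: the input of every learnable radial map.
enveloped_bessel <- function(r, config) {
  bessel_basis(r, config) * polynomial_cutoff(r, config)
}

silu <- function(x) x / (1 + exp(-x))

#' Parameters for the element-agnostic MLP radial basis
#'
#' Seeded random weights for a multi-layer perceptron mapping the enveloped
#' Bessel features to `n_channels x n_paths` outputs.  No biases on any layer,
#' so the envelope's zero at `r_cut` propagates to every output.
#'
#' @param config a [radial_config()]; widths from `config$mlp_widths`.
#' @param n_channels number of uncoupled feature channels.
#' @param seed integer seed.
#' @return list of weight matrices (class `radial_mlp_params`).
#' @export
radial_mlp_params <- function(config, n_channels, seed = 1L) {
  widths <- c(config$n_basis, config$mlp_widths,
              n_channels * config$n_paths)
  with_seed(seed, {
    W <- lapply(seq_len(length(widths) - 1), function(i) {
      matrix(stats::rnorm(widths[i] * widths[i + 1], sd = 1 / sqrt(widths[i])),
             widths[i], widths[i + 1])
    })
    structure(list(weights = W, n_channels = n_channels,
                   n_paths = config$n_paths), class = "radial_mlp_params")
  })
}

#' Element-agnostic MLP radial basis
#'
#' A no-bias MLP (scalar nonlinearity between layers) on the enveloped Bessel
#' features; independent of the chemical elements.
#'
#' @param distances vector of distances (> 0).
#' @param params a [radial_mlp_params()] (or a compatible list of weight
#'   matrices in `$weights`).
#' @param config the [radial_config()] used to build `params`.
#' @param activation scalar nonlinearity between hidden layers (default
#'   [silu]); the output layer is linear.
#' @return array `[n_edges, n_channels, n_paths]`.
#' @export
element_agnostic_radial <- function(distances, params, config,
                                    activation = silu) {
  X <- enveloped_bessel(distances, config)
  W <- params$weights
  if (ncol(X) != nrow(W[[1]])) {
    stop("element_agnostic_radial: weight shape does not match n_basis")
  }
  for (i in seq_along(W)) {
    X <- X %*% W[[i]]
    if (i < length(W)) X <- activation(X)
  }
  array(X, c(length(distances), params$n_channels, params$n_paths))
}

#' Element-dependent linear radial basis
#'
#' `R_[k, path](r) = sum_n W[z_j][k, n, path] R_n(r) f_cut(r)` with one weight
#' block per sender chemical element, realizing a separate radial basis in each
#' embedding channel for each neighbour element.
#'
#' @param distances vector of distances (> 0).
#' @param sender_elements integer element-table indices of the sender atom of
#'   each edge (1-based).
#' @param W list (one entry per element-table slot) of arrays
#'   `[n_channels, n_basis, n_paths]`.
#' @param config the [radial_config()].
#' @return array `[n_edges, n_channels, n_paths]`.
#' @export
element_dependent_radial <- function(distances, sender_elements, W, config) {
  if (any(sender_elements < 1L) || any(sender_elements > length(W))) {
    stop("element_dependent_radial: sender element index outside weight table")
  }
  X <- enveloped_bessel(distances, config)      # [e, n_basis]
  nch <- dim(W[[1]])[1]
  npath <- dim(W[[1]])[3]
  out <- array(X[1] * 0, c(length(distances), nch, npath))
  for (z in unique(sender_elements)) {
    idx <- which(sender_elements == z)
    Wz <- matrix(aperm(W[[z]], c(2, 1, 3)), config$n_basis, nch * npath)
    out[idx, , ] <- X[idx, , drop = FALSE] %*% Wz
  }
  out
}

#' Element-pair distance transform
#'
#' Optional monotone rescaling of the interatomic distance applied before the
#' fixed orthogonal radial basis; this is where element-pair information enters
#' in fixed-orthogonal mode.  Parameterized as `r' = scale(z_i, z_j) * r`
#' (identity by default).
#'
#' @param r distances, > 0.
#' @param z_i,z_j element-table indices of receiver and sender.
#' @param params either `NULL` (identity) or a list with `scale`, a positive
#'   matrix indexed `[z_i, z_j]`.
#' @return transformed distances.
#' @export
distance_transform <- function(r, z_i, z_j, params = NULL) {
  if (any(Re(r) <= 0)) stop("distance_transform: distances must be > 0")
  if (is.null(params)) return(r)
  s <- params$scale
  if (any(s <= 0)) {
    stop("distance_transform: non-monotone parameterization (scale <= 0)")
  }
  r * s[cbind(z_i, z_j)]
}
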