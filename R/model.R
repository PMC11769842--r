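# Model assembly: stacking ACE layers into full potentials with linear
# block-diagonal updates, self-connections, gated nonlinearities and
# (body-ordered) readouts; total energy and complex-step forces.

#' Model configuration and design-space presets
#'
#' The design-space coordinates of a potential: number of layers `T`,
#' correlation order `nu` per layer, angular truncations `l_max`/`L_max`,
#' number of uncoupled channels, embedding/radial/coupling modes, the update
#' nonlinearity, the readout scheme and the pooling normalization.
#'
#' Presets fix recognizable design points:
#' \describe{
#'   \item{`linear_ace`}{`T = 1`, delta embedding, full coupling, fixed
#'     orthogonal radial, invariant (`L_max = 0`) update, per-element linear
#'     readout; `nu` defaults to 3.}
#'   \item{`botnet`}{`nu = 1` per layer, element-dependent linear radial,
#'     strictly linear updates, per-layer linear readouts plus an optional
#'     nonlinear final readout for the residual term.}
#'   \item{`nequip_like`}{`nu = 1`, element-agnostic MLP radial, gated `silu`
#'     updates, `l_max = L_max >= 1`, linear readout of the last layer.}
#'   \item{`schnet_like`}{`nu = 1`, `l_max = L_max = 0` scalar convolutions.}
#' }
#'
#' @param preset one of `"linear_ace"`, `"botnet"`, `"nequip_like"`,
#'   `"schnet_like"`, or `"custom"`.
#' @param elements ascending vector of atomic numbers the model knows.
#' @param r_cut cutoff radius (Angstrom).
#' @param T number of message-passing layers.
#' @param nu correlation order per layer (scalar, recycled).
#' @param l_max,L_max spherical-harmonic and message angular truncations.
#' @param n_channels number of uncoupled channels.
#' @param embedding `"learned"` or `"delta"`.
#' @param radial_mode `"fixed-orthogonal"`, `"agnostic-mlp"` or
#'   `"element-dependent"`.
#' @param coupling `"full"` (delta, all indices coupled) or `"uncoupled"`
#'   (embedded `k` channels).
#' @param nonlinearity update nonlinearity: `"none"`, `"silu"`, `"tanh"` or
#'   `"square"`.
#' @param readout `"per_layer_linear"`, `"last_linear"`, `"botnet"`
#'   (per-layer linear + final nonlinear residual), `"nonlinear"` (silu
#'   readout; infinite Taylor expansion, breaks strict body order - used for
#'   mutation tests) or `"square"` (squared linear readout; the kernel trick,
#'   doubling the correlation order while staying body ordered).
#' @param lambda pooling normalization constant (>= 1); see
#'   [compute_normalization()].
#' @param lambda_mode `"avg"` or `"sqrt_avg"` (how `lambda` is estimated from
#'   data).
#' @param n_basis,p,mlp_widths radial-basis settings ([radial_config()]).
#' @param max_poly_degree delta-mode bound on `sum(n_xi + l_xi)` per tuple.
#' @param envelope `"polynomial"` (smooth cutoff) or `"hard"` (step cutoff;
#'   a deliberately broken variant for the smoothness testbench).
#' @param init `"random"` or `"product-complete"` (structured radial weights
#'   making the invariant channels span the full radial product basis; see the
#'   vignette).
#' @param seed integer seed for parameter initialization.
#' @return object of class `model_config`.
#' @export
model_config <- function(preset = c("custom", "linear_ace", "botnet",
                                    "nequip_like", "schnet_like"),
                         elements, r_cut = 5, T = 2L, nu = 1L,
                         l_max = 2L, L_max = 2L, n_channels = 8L,
                         embedding = NULL, radial_mode = NULL,
                         coupling = NULL, nonlinearity = NULL,
                         readout = NULL, lambda = 1, lambda_mode = "avg",
                         n_basis = 8L, p = 6L, mlp_widths = c(16L, 16L, 16L),
                         max_poly_degree = 12L, envelope = "polynomial",
                         init = "random", seed = 1L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    linear_ace = list(T = 1L, nu = 3L, embedding = "delta",
                      radial_mode = "fixed-orthogonal", coupling = "full",
                      nonlinearity = "none", readout = "per_layer_linear",
                      L_max = 0L),
    botnet = list(nu = 1L, embedding = "learned",
                  radial_mode = "element-dependent", coupling = "uncoupled",
                  nonlinearity = "none", readout = "botnet"),
    nequip_like = list(nu = 1L, embedding = "learned",
                       radial_mode = "agnostic-mlp", coupling = "uncoupled",
                       nonlinearity = "silu", readout = "last_linear",
                       L_max = max(1L, L_max), l_max = max(1L, l_max)),
    schnet_like = list(nu = 1L, embedding = "learned", l_max = 0L, L_max = 0L,
                       radial_mode = "agnostic-mlp", coupling = "uncoupled",
                       nonlinearity = "silu", readout = "per_layer_linear"),
    custom = list()
  )
  pick <- function(name, user, fallback) {
    if (!is.null(user)) user else defaults[[name]] %||% fallback
  }
  cfg <- list(
    preset = preset,
    elements = sort(as.integer(elements)),
    r_cut = r_cut,
    T = as.integer(if (preset == "linear_ace") 1L else T),
    nu = as.integer(pick("nu", if (missing(nu)) NULL else nu, nu)),
    l_max = as.integer(pick("l_max", if (missing(l_max)) NULL else l_max, l_max)),
    L_max = as.integer(pick("L_max", if (missing(L_max)) NULL else L_max, L_max)),
    n_channels = as.integer(n_channels),
    embedding = pick("embedding", embedding, "learned"),
    radial_mode = pick("radial_mode", radial_mode, "agnostic-mlp"),
    coupling = pick("coupling", coupling, "uncoupled"),
    nonlinearity = pick("nonlinearity", nonlinearity, "none"),
    readout = pick("readout", readout, "per_layer_linear"),
    lambda = lambda, lambda_mode = lambda_mode,
    n_basis = as.integer(n_basis), p = as.integer(p),
    mlp_widths = as.integer(mlp_widths),
    max_poly_degree = as.integer(max_poly_degree),
    envelope = envelope,
    init = init, seed = as.integer(seed)
  )
  if (cfg$embedding == "delta" && cfg$coupling == "uncoupled") {
    stop("model_config: delta embedding requires full coupling")
  }
  if (cfg$embedding == "learned" && cfg$coupling == "full") {
    stop("model_config: full index coupling requires the delta embedding")
  }
  if (preset == "botnet" && cfg$nonlinearity != "none") {
    stop("model_config: the botnet preset has strictly linear updates")
  }
  if (preset == "nequip_like" && cfg$l_max != cfg$L_max) {
    stop("model_config: nequip_like preset requires l_max = L_max")
  }
  if (!cfg$nonlinearity %in% c("none", "silu", "tanh", "square")) {
    stop("model_config: unknown nonlinearity '", cfg$nonlinearity, "'")
  }
  structure(cfg, class = "model_config")
}

model_radial_config <- function(config, n_paths) {
  radial_config(r_cut = config$r_cut, n_basis = config$n_basis, p = config$p,
                mode = config$radial_mode, mlp_widths = config$mlp_widths,
                n_paths = n_paths,
                envelope = config$envelope %||% "polynomial")
}

#' Assemble a parameterized potential from a configuration
#'
#' Composes embedding, `T` ACE layers (one-particle basis, pooling, products,
#' symmetrization, message, linear update with optional self-connection and
#' gate) and the readout scheme into a callable potential with seeded,
#' deterministic initialization.
#'
#' @param config a [model_config()].
#' @return object of class `equiace_model` with `$config` and `$params`.
#' @export
assemble_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  n_elem <- length(config$elements)
  nch <- config$n_channels
  params <- list()
  with_seed(config$seed, {
    if (config$embedding == "delta") {
      params$embedding <- diag(n_elem)
    } else {
      params$embedding <- matrix(stats::rnorm(n_elem * nch), n_elem, nch)
    }
    params$layers <- vector("list", config$T)
    sender_Ls <- 0L
    for (t in seq_len(config$T)) {
      layer <- list()
      if (config$embedding == "delta") {
        layer$paths <- NULL
        layer$radial <- NULL   # fixed orthogonal basis, no parameters
      } else {
        paths <- layer_paths(config$l_max, sender_Ls, config$L_max)
        layer$paths <- paths
        rc <- model_radial_config(config, nrow(paths))
        if (config$radial_mode == "agnostic-mlp") {
          layer$radial <- radial_mlp_params(rc, nch, seed = config$seed + 100 + t)
        } else {
          layer$radial <- lapply(seq_len(n_elem), function(z) {
            array(stats::rnorm(nch * config$n_basis * nrow(paths),
                               sd = 1 / sqrt(config$n_basis)),
                  c(nch, config$n_basis, nrow(paths)))
          })
        }
        # block-diagonal update and element-conditioned self-connection
        layer$W <- array(stats::rnorm(nch * nch * (config$L_max + 1),
                                      sd = 1 / sqrt(nch)),
                         c(nch, nch, config$L_max + 1))
        layer$S <- lapply(seq_len(n_elem), function(z) {
          array(stats::rnorm(nch * nch * (config$L_max + 1),
                             sd = 1 / sqrt(nch)),
                c(nch, nch, config$L_max + 1))
        })
        if (config$nu > 1) {
          layer$message_weights <- NULL  # filled lazily per tuple table
        }
        sender_Ls <- 0:config$L_max
      }
      params$layers[[t]] <- layer
    }
    if (config$embedding == "delta") {
      params$ace_weights <- NULL  # per-element B-basis weights, set below
    }
    # readouts
    if (config$readout %in% c("per_layer_linear", "botnet", "nonlinear",
                              "square")) {
      params$readout <- lapply(seq_len(config$T), function(t) {
        stats::rnorm(nch, sd = 1 / sqrt(nch))
      })
    } else {
      params$readout <- c(vector("list", config$T - 1),
                          list(stats::rnorm(nch, sd = 1 / sqrt(nch))))
    }
    if (config$readout == "botnet") {
      params$readout_mlp <- list(
        W1 = matrix(stats::rnorm(nch * 16, sd = 1 / sqrt(nch)), nch, 16),
        W2 = matrix(stats::rnorm(16, sd = 1 / 4), 16, 1)
      )
    }
    params$e0 <- stats::setNames(rep(0, n_elem), config$elements)
  })
  model <- structure(list(config = config, params = params),
                     class = "equiace_model")
  if (config$embedding == "delta") {
    model <- init_delta_basis(model)
  }
  if (config$init == "product-complete") {
    model <- product_complete_init(model)
  }
  model
}

# Delta-mode (linear ACE) basis table: entry grid, tuple set and per-element
# weights over the invariant symmetrized basis.
init_delta_basis <- function(model) {
  cfg <- model$config
  n_elem <- length(cfg$elements)
  entries <- expand.grid(n = seq_len(cfg$n_basis), z = seq_len(n_elem),
                         l = 0:cfg$l_max)
  tuples <- list()
  for (nu in seq_len(cfg$nu)) {
    tps <- sorted_tuples(nrow(entries), nu)
    keep <- vapply(tps, function(tp) {
      degs <- entries$l[tp]
      if (sum(entries$n[tp] + degs) > cfg$max_poly_degree) return(FALSE)
      length(coupling_schemes(degs, 0L)) > 0 && sum(degs) %% 2 == 0
    }, TRUE)
    tuples <- c(tuples, tps[keep])
  }
  # number of invariant basis functions = sum of path counts
  n_bfun <- sum(vapply(tuples, function(tp) {
    length(generalized_coupling(entries$l[tp], 0L)$tensors)
  }, 1L))
  model$params$basis <- list(entries = entries, tuples = tuples,
                             n_bfun = n_bfun)
  model$params$ace_weights <- with_seed(cfg$seed + 7, {
    lapply(seq_len(n_elem), function(z) stats::rnorm(n_bfun, sd = 1))
  })
  model
}

# Structured radial initialization for nu = 1, T = 2 embedded models:
# channel k = (a, b, l0) reads Bessel function b in layer 1 (all paths) and
# Bessel function a in layer 2, but only on the invariant path with l = l0.
# The layer-2 invariant channels then span the complete tensor-product radial
# basis {R_a(r1) R_b(r2) P_l(cos theta)}; updates become the identity and
# self-connections vanish so the span survives to the readout.
product_complete_init <- function(model) {
  cfg <- model$config
  if (cfg$T != 2L || cfg$nu != 1L || cfg$embedding != "learned" ||
      cfg$radial_mode != "element-dependent") {
    stop("product-complete init needs T = 2, nu = 1, element-dependent radial")
  }
  nb <- cfg$n_basis
  nl <- cfg$l_max + 1L
  nch_needed <- nb * nb * nl
  if (cfg$n_channels != nch_needed) {
    stop("product-complete init needs n_channels = n_basis^2 * (l_max + 1) = ",
         nch_needed)
  }
  grid <- expand.grid(a = seq_len(nb), b = seq_len(nb), l0 = 0:cfg$l_max)
  n_elem <- length(cfg$elements)
  model$params$embedding <- matrix(1, n_elem, cfg$n_channels)
  for (t in 1:2) {
    paths <- model$params$layers[[t]]$paths
    W <- array(0, c(cfg$n_channels, nb, nrow(paths)))
    for (p in seq_len(nrow(paths))) {
      if (t == 1) {
        W[cbind(seq_len(nrow(grid)), grid$b, p)] <- 1
      } else if (paths$L[p] == 0) {
        sel <- grid$l0 == paths$l1[p]
        W[cbind(which(sel), grid$a[sel], p)] <- 1
      }
    }
    model$params$layers[[t]]$radial <- lapply(seq_len(n_elem), function(z) W)
    ident <- array(0, c(cfg$n_channels, cfg$n_channels, cfg$L_max + 1))
    for (L in 0:cfg$L_max) ident[, , L + 1] <- diag(cfg$n_channels)
    model$params$layers[[t]]$W <- ident
    model$params$layers[[t]]$S <- lapply(seq_len(n_elem), function(z) {
      array(0, c(cfg$n_channels, cfg$n_channels, cfg$L_max + 1))
    })
  }
  model
}

#' Linear update with block-diagonal weights
#'
#' `h_next[i, k, L, M] = sum_k' W[k, k', L] m[i, k', L, M]`: channels mix, but
#' no mixing across `L` or `M` (the weight array is structurally block
#' diagonal).
#'
#' @param message feature list keyed by degree.
#' @param W_blockdiag array `[n_channels, n_channels, L_max + 1]`.
#' @return feature list.
#' @export
linear_update <- function(message, W_blockdiag) {
  out <- message
  for (Lc in names(message)) {
    L <- as.integer(Lc)
    x <- message[[Lc]]
    d <- dim(x)
    if (L + 1 > dim(W_blockdiag)[3] || d[2] != dim(W_blockdiag)[1]) {
      stop("linear_update: weight shape mismatch")
    }
    xm <- matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3])
    ym <- W_blockdiag[, , L + 1] %*% xm
    out[[Lc]] <- aperm(array(ym, c(d[2], d[1], d[3])), c(2, 1, 3))
  }
  out
}

#' Element-conditioned residual self-connection
#'
#' `h_next <- updated + S(z_i) h_prev`, with `S` block diagonal in `L` and one
#' block per chemical element.
#'
#' @param updated_features feature list (the linear update of the message).
#' @param previous_state feature list from the previous layer.
#' @param attrs a [one_hot_attributes()].
#' @param S_weights list per element of arrays
#'   `[n_channels, n_channels, L_max + 1]`.
#' @return feature list.
#' @export
self_connection <- function(updated_features, previous_state, attrs,
                            S_weights) {
  out <- updated_features
  for (Lc in names(previous_state)) {
    if (is.null(out[[Lc]])) next
    L <- as.integer(Lc)
    xp <- previous_state[[Lc]]
    d <- dim(xp)
    add <- array(xp[1] * 0, dim(out[[Lc]]))
    for (z in unique(attrs$indices)) {
      rows <- which(attrs$indices == z)
      xm <- matrix(aperm(xp[rows, , , drop = FALSE], c(2, 1, 3)),
                   d[2], length(rows) * d[3])
      ym <- S_weights[[z]][, , L + 1] %*% xm
      add[rows, , ] <- aperm(array(ym, c(dim(add)[2], length(rows), d[3])),
                             c(2, 1, 3))
    }
    out[[Lc]] <- out[[Lc]] + add
  }
  out
}

#' Gated equivariant nonlinearity
#'
#' Scalar (`L = 0`) channels pass through the scalar nonlinearity elementwise;
#' each `L > 0` channel is multiplied by a scalar gate computed from its own
#' `L = 0` channel.  `kind = "none"` is the identity.  `kind = "square"` is
#' the finite-Taylor (kernel-trick) nonlinearity: invariants are squared and
#' equivariants gated by a linear scalar, which doubles the body order while
#' keeping the expansion finite.
#'
#' @param features feature list keyed by degree.
#' @param kind one of `"none"`, `"silu"`, `"tanh"`, `"square"`.
#' @return feature list.
#' @export
gated_nonlinearity <- function(features, kind = c("none", "silu", "tanh",
                                                  "square")) {
  kind <- match.arg(kind)
  if (kind == "none") return(features)
  out <- features
  scal <- features[["0"]]
  act <- switch(kind, silu = silu, tanh = tanh, square = function(x) x * x)
  gate <- switch(kind,
                 silu = function(x) 1 / (1 + exp(-x)),   # sigmoid gate
                 tanh = tanh,
                 square = function(x) x)                 # linear gate
  for (Lc in names(features)) {
    if (Lc == "0") {
      out[[Lc]] <- array(act(scal), dim(scal))
    } else {
      g <- gate(scal[, , 1])
      out[[Lc]] <- features[[Lc]] * as.vector(g)
    }
  }
  out
}

#' Per-atom site energies from the layer states
#'
#' Linear readouts act only on the invariant (`L = 0`) channels, giving the
#' body-ordered per-layer terms; the `botnet` scheme adds a final nonlinear
#' (silu MLP) readout of the last layer's invariants, the residual of the
#' body-order expansion.  The `nonlinear` scheme applies silu inside every
#' readout (an intentionally non-body-ordered variant).
#'
#' @param states_per_layer list over layers of feature lists.
#' @param scheme readout scheme (see [model_config()]).
#' @param params model readout parameters (`readout`, optionally
#'   `readout_mlp`).
#' @return matrix `[n_atoms, n_terms]` of per-layer site-energy contributions
#'   (the residual term last when present).
#' @export
readout <- function(states_per_layer, scheme, params) {
  Tn <- length(states_per_layer)
  cols <- list()
  for (t in seq_len(Tn)) {
    w <- params$readout[[t]]
    if (is.null(w)) next
    h0 <- states_per_layer[[t]][["0"]][, , 1, drop = FALSE]
    h0 <- array(h0, dim(h0)[1:2])
    if (scheme == "nonlinear") {
      cols[[length(cols) + 1]] <- silu(h0) %*% w
    } else if (scheme == "square") {
      # kernel trick: squaring an invariant readout doubles the correlation
      # order while keeping the Taylor expansion finite
      cols[[length(cols) + 1]] <- (h0 %*% w)^2
    } else {
      cols[[length(cols) + 1]] <- h0 %*% w
    }
  }
  if (scheme == "botnet") {
    h0 <- states_per_layer[[Tn]][["0"]][, , 1, drop = FALSE]
    h0 <- array(h0, dim(h0)[1:2])
    mlp <- params$readout_mlp
    cols[[length(cols) + 1]] <- silu(h0 %*% mlp$W1) %*% mlp$W2
  }
  do.call(cbind, cols)
}

# ---- full forward pass ------------------------------------------------------

# Forward evaluation on (possibly complex) positions with a fixed neighbour
# list.  Returns site energies, per-layer states and contribution columns.
model_forward <- function(model, config, nl = NULL, positions = NULL,
                          store_states = FALSE) {
  cfg <- model$config
  par <- model$params
  if (is.null(nl)) nl <- build_neighbour_list(config, cfg$r_cut)
  if (is.null(positions)) positions <- config$positions
  nat <- nrow(positions)
  attrs <- one_hot_attributes(config$atomic_numbers, cfg$elements)
  disp <- edge_displacements(nl, positions, config$cell)
  r <- row_norms(disp)
  if (any(Re(r) < 1e-6)) stop("model_forward: overlapping atoms (r < 1e-6)")
  nl_eval <- nl
  nl_eval$displacements <- disp
  nl_eval$distances <- r
  lam <- max(cfg$lambda, 1)

  if (cfg$embedding == "delta") {
    return(delta_forward(model, config, nl_eval, attrs, lam, store_states))
  }

  h <- initial_embedding(attrs, par$embedding)
  states <- vector("list", cfg$T)
  rc_base <- model_radial_config(cfg, 1L)
  for (t in seq_len(cfg$T)) {
    layer <- par$layers[[t]]
    paths <- layer$paths
    rc <- model_radial_config(cfg, nrow(paths))
    if (cfg$radial_mode == "agnostic-mlp") {
      act <- if (cfg$nonlinearity %in% c("silu", "none", "square")) silu else tanh
      R <- element_agnostic_radial(r, layer$radial, rc, activation = act)
    } else {
      zj <- attrs$indices[nl$senders]
      R <- element_dependent_radial(r, zj, layer$radial, rc)
    }
    if (cfg$nu == 1L) {
      m <- nequip_convolution(nl_eval, list(h = h), R, cfg$l_max, cfg$L_max,
                              lambda = lam)
    } else {
      eb <- one_particle_basis(t - 1L, nl_eval, list(h = h, attrs = attrs), R,
                               list(l_max = cfg$l_max, L_max = cfg$L_max,
                                    mode = "embedded"))
      A <- pool_atomic_basis(eb, nl$receivers, lam, nat)
      PB <- product_basis(A, cfg$nu, max_L = cfg$L_max)
      m <- list()
      for (L in 0:cfg$L_max) {
        SB <- symmetrize(PB, L)
        if (!length(SB$values)) next
        w <- message_weights(model, t, L, length(SB$values))
        m[[as.character(L)]] <- form_message(SB, w)
      }
    }
    h_new <- linear_update(m, layer$W)
    h_new <- self_connection(h_new, h, attrs, layer$S)
    h_new <- gated_nonlinearity(h_new, cfg$nonlinearity)
    h <- h_new
    states[[t]] <- h
  }
  scheme <- switch(cfg$readout, botnet = "botnet", nonlinear = "nonlinear",
                   square = "square", "linear")
  contrib <- readout(states, scheme, par)
  e0_site <- par$e0[match(config$atomic_numbers, cfg$elements)]
  site <- e0_site + rowSums(contrib)
  list(site_energies = site, contributions = contrib,
       e0_site = e0_site,
       states = if (store_states) states else NULL,
       invariants = invariant_features(states))
}

# Seeded per-(layer, L) message weights for nu >= 2 embedded engines,
# cached on the model's environment-free params by deterministic regeneration.
message_weights <- function(model, t, L, n_bfun) {
  cfg <- model$config
  with_seed(cfg$seed + 1000 * t + L, {
    matrix(stats::rnorm(cfg$n_channels * n_bfun, sd = 1 / sqrt(n_bfun)),
           cfg$n_channels, n_bfun)
  })
}

# Invariant (L = 0) channels of every layer, the features linear readouts see.
invariant_features <- function(states) {
  do.call(cbind, lapply(states, function(h) {
    x <- h[["0"]]
    array(x[, , 1], dim(x)[1:2])
  }))
}

# Linear-ACE forward: A basis over (n, z, l) entries, bounded tuples,
# invariant symmetrization, per-element weights.
delta_forward <- function(model, config, nl_eval, attrs, lam, store_states) {
  cfg <- model$config
  par <- model$params
  nat <- nrow(config$positions)
  rc <- model_radial_config(cfg, 1L)
  Rb <- enveloped_bessel(nl_eval$distances, rc)
  h <- initial_embedding(attrs, par$embedding)
  eb <- one_particle_basis(0L, nl_eval, list(h = h, attrs = attrs), Rb,
                           list(l_max = cfg$l_max, L_max = cfg$L_max,
                                mode = "delta"))
  A <- pool_atomic_basis(eb, nl_eval$receivers, lam, nat)
  basis <- par$basis
  Bcols <- delta_invariants(A, basis)
  w <- par$ace_weights
  site <- numeric(nat) * Bcols[1]
  for (z in unique(attrs$indices)) {
    rows <- which(attrs$indices == z)
    site[rows] <- Bcols[rows, , drop = FALSE] %*% w[[z]]
  }
  e0_site <- par$e0[match(config$atomic_numbers, cfg$elements)]
  site <- site + e0_site
  list(site_energies = site, contributions = matrix(site - e0_site),
       e0_site = e0_site, states = NULL, invariants = Bcols,
       A = if (store_states) A else NULL)
}

# Invariant symmetrized features for every tuple of the delta basis table:
# matrix [n_atoms, n_bfun].
delta_invariants <- function(A, basis) {
  cols <- list()
  for (tp in basis$tuples) {
    PB <- product_basis(A, length(tp), tuple_index_set = list(tp))
    SB <- symmetrize(PB, 0L)
    for (v in SB$values) cols[[length(cols) + 1]] <- v[, 1, 1]
  }
  do.call(cbind, cols)
}

#' Total energy of a configuration
#'
#' `E = sum_z n_z E0_z + sum_i sum_t R_t(sigma_i^(t)) (+ E_rest)`, with the
#' per-layer terms reported separately so the body-order structure is
#' auditable.
#'
#' @param model an [assemble_model()] result.
#' @param config an [atomic_configuration()].
#' @return object of class `energy_result`: `energy` (eV), `site_energies`,
#'   `contributions` (per-atom, per-term matrix), `e0` (reference part).
#' @export
total_energy <- function(model, config) {
  unknown <- setdiff(unique(config$atomic_numbers), model$config$elements)
  if (length(unknown)) {
    stop("total_energy: element(s) not in the model table: ",
         paste(unknown, collapse = ", "))
  }
  fw <- model_forward(model, config)
  structure(list(energy = sum(fw$site_energies),
                 site_energies = fw$site_energies,
                 contributions = fw$contributions,
                 e0 = sum(fw$e0_site)),
            class = "energy_result")
}

#' @export
print.energy_result <- function(x, ...) {
  cat(sprintf("energy_result: E = %.8f eV over %d atoms\n",
              x$energy, length(x$site_energies)))
  invisible(x)
}

#' Forces from machine-precision differentiation
#'
#' `F = -dE/dr` evaluated by complex-step differentiation of the forward pass
#' (imaginary step 1e-100): derivative values exact to float64 round-off, with
#' the neighbour-list graph held fixed (valid everywhere except exactly at a
#' cutoff crossing, where the energy is continuous but the graph changes).
#'
#' @param model an [assemble_model()] result.
#' @param config an [atomic_configuration()].
#' @param batch number of coordinates perturbed per forward evaluation (each
#'   in an independent replica of the configuration).
#' @return `n_atoms x 3` matrix, eV/Angstrom.
#' @export
compute_forces <- function(model, config, batch = 12L) {
  nl <- build_neighbour_list(config, model$config$r_cut)
  if (length(nl$distances) && min(nl$distances) < 1e-6) {
    stop("compute_forces: overlapping atoms")
  }
  nat <- nrow(config$positions)
  ncoord <- 3L * nat
  grad <- numeric(ncoord)
  idx <- split(seq_len(ncoord), ceiling(seq_len(ncoord) / batch))
  for (chunk in idx) {
    k <- length(chunk)
    # disjoint union of k replicas, one perturbed coordinate each
    pos <- config$positions[rep(seq_len(nat), k), , drop = FALSE] + 0i
    for (j in seq_len(k)) {
      coord <- chunk[j]
      a <- (coord - 1L) %% nat + 1L
      d <- (coord - 1L) %/% nat + 1L
      pos[(j - 1L) * nat + a, d] <- pos[(j - 1L) * nat + a, d] + CSTEP * 1i
    }
    big_nl <- replicate_neighbour_list(nl, nat, k)
    big_cfg <- replicate_config(config, k)
    fw <- model_forward(model, big_cfg, nl = big_nl, positions = pos)
    site <- fw$site_energies
    for (j in seq_len(k)) {
      rows <- ((j - 1L) * nat + 1L):(j * nat)
      grad[chunk[j]] <- sum(Im(site[rows])) / CSTEP
    }
  }
  # grad indexed by (atom, coordinate) with atom fastest
  -matrix(grad, nat, 3)
}

replicate_neighbour_list <- function(nl, nat, k) {
  ne <- length(nl$receivers)
  off <- rep((0:(k - 1)) * nat, each = ne)
  list(receivers = rep(nl$receivers, k) + off,
       senders = rep(nl$senders, k) + off,
       shifts = nl$shifts[rep(seq_len(ne), k), , drop = FALSE],
       displacements = nl$displacements[rep(seq_len(ne), k), , drop = FALSE],
       distances = rep(nl$distances, k),
       r_cut = nl$r_cut, n_atoms = nat * k)
}

replicate_config <- function(config, k) {
  atomic_configuration(
    positions = config$positions[rep(seq_len(nrow(config$positions)), k), ,
                                 drop = FALSE],
    atomic_numbers = rep(config$atomic_numbers, k),
    cell = config$cell,
    pbc = config$pbc
  )
}

#' Predicted energy, forces and per-atom decomposition
#'
#' Convenience wrapper returning the full [total_energy()] result augmented
#' with [compute_forces()].
#'
#' @inheritParams total_energy
#' @return `energy_result` with a `forces` field.
#' @export
predict_potential <- function(model, config) {
  res <- total_energy(model, config)
  res$forces <- compute_forces(model, config)
  res
}
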