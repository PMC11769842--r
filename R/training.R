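# Reference energies, normalization statistics, the energy/force loss, and
# deterministic fitting of the readout (output) weights by penalized least
# squares on energies and forces.  Models with linear readouts are linear in
# those weights, so the fit is convex; the same quadratic objective can also
# be minimized by plain gradient descent for a step-by-step training log.

#' Per-element reference energies by least squares
#'
#' Solves `E_total ~ sum_z n_z E0_z` over all labelled frames.  A
#' rank-deficient composition matrix (e.g. all frames with the same
#' stoichiometry) falls back to the minimum-norm solution with a warning.
#'
#' @param configs list of [atomic_configuration()] with `energy` labels.
#' @param elements element table (defaults to all elements present).
#' @return named vector of E0 per element (eV).
#' @export
estimate_reference_energies <- function(configs, elements = NULL) {
  labelled <- Filter(function(cf) !is.null(cf$energy), configs)
  if (!length(labelled)) {
    stop("estimate_reference_energies: no energy labels in the dataset")
  }
  if (is.null(elements)) {
    elements <- sort(unique(unlist(lapply(labelled, `[[`, "atomic_numbers"))))
  }
  N <- t(vapply(labelled, function(cf) {
    vapply(elements, function(z) sum(cf$atomic_numbers == z), 1)
  }, numeric(length(elements))))
  N <- matrix(N, nrow = length(labelled))
  y <- vapply(labelled, `[[`, 1, "energy")
  sv <- svd(N)
  tol <- max(dim(N)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (rank < length(elements)) {
    warning("estimate_reference_energies: rank-deficient composition; ",
            "returning the minimum-norm solution")
  }
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  e0 <- sv$v %*% (dinv * crossprod(sv$u, y))
  stats::setNames(as.numeric(e0), elements)
}

#' Pooling-normalization statistics from a dataset
#'
#' `lambda` is the mean neighbour count over all atoms of all frames
#' (`mode = "avg"`) or its square root (`mode = "sqrt_avg"`), clamped to 1
#' from below so isolated-atom datasets stay well defined.
#'
#' @param configs list of [atomic_configuration()].
#' @param r_cut neighbour cutoff (Angstrom).
#' @param mode `"avg"` or `"sqrt_avg"`.
#' @return object of class `normalization_stats`: `lambda`, `mode`,
#'   `mean_neighbours`, `force_rms` (NA without force labels).
#' @export
compute_normalization <- function(configs, r_cut, mode = c("avg", "sqrt_avg")) {
  mode <- match.arg(mode)
  counts <- unlist(lapply(configs, function(cf) {
    nl <- build_neighbour_list(cf, r_cut)
    tabulate(nl$receivers, nbins = nrow(cf$positions))
  }))
  mn <- mean(counts)
  lam <- if (mode == "avg") mn else sqrt(mn)
  lam <- max(lam, 1)
  f <- unlist(lapply(configs, function(cf) cf$forces))
  structure(list(lambda = lam, mode = mode, mean_neighbours = mn,
                 force_rms = if (length(f)) sqrt(mean(f^2)) else NA_real_),
            class = "normalization_stats")
}

#' Loss configuration
#'
#' @param energy_weight,force_weight non-negative weights, not both zero.
#' @param per_atom_energy compare total or per-atom energies.
#' @return list of class `loss_config`.
#' @export
loss_config <- function(energy_weight = 1, force_weight = 10,
                        per_atom_energy = TRUE) {
  stopifnot(energy_weight >= 0, force_weight >= 0,
            energy_weight + force_weight > 0)
  structure(list(energy_weight = energy_weight, force_weight = force_weight,
                 per_atom_energy = per_atom_energy), class = "loss_config")
}

#' Weighted energy/force loss for one frame
#'
#' `energy_weight * (dE [/n_atoms])^2 + force_weight * mean(dF^2)`.
#'
#' @param prediction list with `energy` and optionally `forces`.
#' @param labels an [atomic_configuration()] carrying the reference labels.
#' @param cfg a [loss_config()].
#' @return non-negative scalar.
#' @export
loss <- function(prediction, labels, cfg = loss_config()) {
  out <- 0
  if (cfg$energy_weight > 0) {
    if (is.null(labels$energy)) stop("loss: energy label missing")
    de <- prediction$energy - labels$energy
    if (cfg$per_atom_energy) de <- de / nrow(labels$positions)
    out <- out + cfg$energy_weight * de^2
  }
  if (cfg$force_weight > 0) {
    if (is.null(labels$forces)) stop("loss: force labels missing")
    df <- prediction$forces - labels$forces
    out <- out + cfg$force_weight * mean(df^2)
  }
  out
}

# ---- design matrices for the readout-linear parameterization ----------------

# Layout of the linear parameter vector: either shared readout weights
# (one block per layer with a readout) or per-element delta weights; plus one
# E0 column per element.
param_layout <- function(model) {
  cfg <- model$config
  if (cfg$embedding == "delta") {
    nb <- model$params$basis$n_bfun
    list(kind = "delta", n_w = nb * length(cfg$elements), n_bfun = nb)
  } else {
    slots <- which(!vapply(model$params$readout, is.null, TRUE))
    list(kind = "shared", n_w = length(slots) * cfg$n_channels, slots = slots)
  }
}

# Energy design row: features such that E = row %*% c(w, e0).
energy_row <- function(model, config, layout, fw = NULL) {
  cfg <- model$config
  if (is.null(fw)) fw <- model_forward(model, config)
  phi <- fw$invariants
  if (layout$kind == "delta") {
    zidx <- match(config$atomic_numbers, cfg$elements)
    blocks <- lapply(seq_along(cfg$elements), function(z) {
      rows <- zidx == z
      if (any(rows)) colSums(phi[rows, , drop = FALSE]) else
        numeric(ncol(phi))
    })
    w_part <- unlist(blocks)
  } else {
    w_part <- colSums(phi)
  }
  counts <- vapply(cfg$elements, function(z) sum(config$atomic_numbers == z), 1)
  c(w_part, counts)
}

# Force design rows (3 n_atoms x n_params): -d(features)/d(coordinates),
# by batched complex-step differentiation of the forward pass.  The real part
# of the first replica also yields the (exact) energy design row, returned as
# attribute "e_row" so one pass serves both.
force_rows <- function(model, config, layout, batch = 12L) {
  cfg <- model$config
  nl <- build_neighbour_list(config, cfg$r_cut)
  nat <- nrow(config$positions)
  ncoord <- 3L * nat
  npar <- layout$n_w + length(cfg$elements)
  J <- matrix(0, ncoord, npar)
  zidx <- match(config$atomic_numbers, cfg$elements)
  chunks <- split(seq_len(ncoord), ceiling(seq_len(ncoord) / batch))
  e_row <- NULL
  group_cols <- function(block) {
    if (layout$kind == "delta") {
      unlist(lapply(seq_along(cfg$elements), function(z) {
        rr <- zidx == z
        if (any(rr)) colSums(block[rr, , drop = FALSE]) else
          numeric(ncol(block))
      }))
    } else {
      colSums(block)
    }
  }
  for (chunk in chunks) {
    k <- length(chunk)
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
    phi <- fw$invariants
    for (j in seq_len(k)) {
      rows <- ((j - 1L) * nat + 1L):(j * nat)
      block <- Im(phi[rows, , drop = FALSE]) / CSTEP
      J[chunk[j], seq_len(layout$n_w)] <- group_cols(block)
    }
    if (is.null(e_row)) {
      # imaginary steps underflow in the real part, so Re() is exact
      counts <- vapply(cfg$elements, function(z)
        sum(config$atomic_numbers == z), 1)
      e_row <- c(group_cols(Re(phi[seq_len(nat), , drop = FALSE])), counts)
    }
  }
  # coordinates indexed atom-fastest, matching as.vector(forces)
  structure(-J, e_row = e_row)
}

# Write a solved linear parameter vector back into the model.
set_linear_params <- function(model, layout, w_full) {
  cfg <- model$config
  w <- w_full[seq_len(layout$n_w)]
  e0 <- w_full[layout$n_w + seq_along(cfg$elements)]
  if (layout$kind == "delta") {
    nb <- layout$n_bfun
    model$params$ace_weights <- lapply(seq_along(cfg$elements), function(z) {
      w[((z - 1) * nb + 1):(z * nb)]
    })
  } else {
    nch <- cfg$n_channels
    for (s in seq_along(layout$slots)) {
      t <- layout$slots[s]
      model$params$readout[[t]] <- w[((s - 1) * nch + 1):(s * nch)]
    }
  }
  model$params$e0 <- stats::setNames(as.numeric(e0), cfg$elements)
  model
}

# Stack the weighted design for a dataset.
build_design <- function(model, configs, lcfg, batch = 6L) {
  layout <- param_layout(model)
  X <- list(); y <- list()
  for (cf in configs) {
    nat <- nrow(cf$positions)
    want_E <- lcfg$energy_weight > 0 && !is.null(cf$energy)
    want_F <- lcfg$force_weight > 0 && !is.null(cf$forces)
    Fr <- NULL
    if (want_F) Fr <- force_rows(model, cf, layout, batch = batch)
    if (want_E) {
      scale <- sqrt(lcfg$energy_weight) / if (lcfg$per_atom_energy) nat else 1
      er <- if (!is.null(Fr)) attr(Fr, "e_row") else
        energy_row(model, cf, layout)
      X[[length(X) + 1]] <- er * scale
      y[[length(y) + 1]] <- cf$energy * scale
    }
    if (want_F) {
      scale <- sqrt(lcfg$force_weight / (3 * nat))
      X[[length(X) + 1]] <- unclass(Fr) * scale
      y[[length(y) + 1]] <- as.vector(cf$forces) * scale
    }
  }
  list(X = do.call(rbind, X), y = unlist(y), layout = layout)
}

dataset_loss <- function(model, configs, lcfg, forces = TRUE) {
  vals <- vapply(configs, function(cf) {
    pred <- list(energy = total_energy(model, cf)$energy,
                 forces = if (forces && lcfg$force_weight > 0)
                   compute_forces(model, cf) else NULL)
    cfg2 <- lcfg
    if (is.null(pred$forces)) cfg2$force_weight <- 0
    loss(pred, cf, cfg2)
  }, 1)
  mean(vals)
}

#' Fit a potential to labelled configurations
#'
#' Estimates the pooling normalization from the training set, then minimizes
#' the weighted energy/force squared loss over the model's readout weights and
#' per-element reference energies.  The model is linear in those parameters,
#' so `method = "lsq"` solves the problem in closed form (QR with a small
#' ridge); `method = "gd"` runs deterministic full-batch gradient descent on
#' the identical objective and logs the loss per epoch.  Internal (radial,
#' update, embedding) weights keep their seeded or structured initialization.
#'
#' @param model an [assemble_model()] result with a readout linear in its
#'   weights (`per_layer_linear` or `last_linear`).
#' @param train_configs,val_configs lists of labelled
#'   [atomic_configuration()]; `val_configs` may be `NULL`.
#' @param optimizer_cfg list with `method` ("lsq" or "gd"), `ridge`
#'   (default 1e-10), `epochs`, `lr` and a [loss_config()] under `loss`.
#' @param seed integer seed controlling frame order and any stochastic choice.
#' @return object of class `training_state`: the fitted `model`, `history`
#'   (data.frame of per-epoch train/validation loss), `lambda`, `seed`.
#' @export
fit <- function(model, train_configs, val_configs = NULL,
                optimizer_cfg = list(), seed = 1L) {
  stopifnot(length(train_configs) > 0)
  cfg <- model$config
  if (!cfg$readout %in% c("per_layer_linear", "last_linear")) {
    stop("fit: readout scheme '", cfg$readout,
         "' is not linear in its weights; use a linear-readout variant")
  }
  method <- optimizer_cfg$method %||% "lsq"
  ridge <- optimizer_cfg$ridge %||% 1e-10
  lcfg <- optimizer_cfg$loss %||% loss_config()
  batch <- optimizer_cfg$batch %||% 12L
  norm <- compute_normalization(train_configs, cfg$r_cut,
                                mode = cfg$lambda_mode)
  model$config$lambda <- norm$lambda
  order_idx <- with_seed(seed, sample(seq_along(train_configs)))
  des <- build_design(model, train_configs[order_idx], lcfg, batch = batch)
  X <- des$X; y <- des$y
  npar <- ncol(X)
  if (method == "lsq") {
    Xa <- rbind(X, diag(sqrt(ridge), npar))
    ya <- c(y, numeric(npar))
    qr_fit <- qr(Xa, LAPACK = TRUE)
    w <- qr.coef(qr_fit, ya)
    w[is.na(w)] <- 0
    model <- set_linear_params(model, des$layout, w)
    hist <- data.frame(epoch = 1L,
                       train = dataset_loss(model, train_configs, lcfg),
                       val = if (length(val_configs))
                         dataset_loss(model, val_configs, lcfg) else NA_real_)
    best <- model
  } else if (method == "gd") {
    epochs <- optimizer_cfg$epochs %||% 200L
    G <- crossprod(X) + diag(ridge, npar)
    b <- crossprod(X, y)
    lr <- optimizer_cfg$lr %||% (1 / (2 * max(rowSums(abs(G)))))
    w <- numeric(npar)
    hist <- data.frame(epoch = integer(0), train = numeric(0),
                       val = numeric(0))
    best <- NULL; best_val <- Inf
    for (ep in seq_len(epochs)) {
      grad <- G %*% w - b
      w <- w - lr * as.numeric(grad)
      if (any(!is.finite(w))) {
        stop("fit: optimization diverged (non-finite parameters) at epoch ", ep)
      }
      train_obj <- mean((X %*% w - y)^2)
      cand <- set_linear_params(model, des$layout, w)
      val_obj <- if (length(val_configs))
        dataset_loss(cand, val_configs, lcfg) else train_obj
      hist <- rbind(hist, data.frame(epoch = ep, train = train_obj,
                                     val = val_obj))
      if (val_obj <= best_val) { best_val <- val_obj; best <- cand }
    }
    model <- best
  } else {
    stop("fit: unknown method '", method, "'")
  }
  if (any(!is.finite(hist$train))) {
    stop("fit: loss diverged to a non-finite value")
  }
  structure(list(model = model, history = hist, lambda = norm$lambda,
                 normalization = norm, seed = as.integer(seed)),
            class = "training_state")
}

#' @export
print.training_state <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf(
    "training_state: %d epoch(s), final train loss %.3e, lambda = %.3f\n",
    n, x$history$train[n], x$lambda))
  invisible(x)
}

#' Energy/force errors of a model on a dataset
#'
#' @param model a fitted model.
#' @param configs labelled configurations.
#' @return list with `energy_rmse` (eV/atom), `force_rmse`, `force_rms_label`
#'   (eV/Angstrom) and `force_rmse_relative`.
#' @export
evaluate_errors <- function(model, configs) {
  de <- c(); df <- c(); fl <- c()
  for (cf in configs) {
    res <- total_energy(model, cf)
    if (!is.null(cf$energy)) {
      de <- c(de, (res$energy - cf$energy) / nrow(cf$positions))
    }
    if (!is.null(cf$forces)) {
      Fp <- compute_forces(model, cf)
      df <- c(df, as.vector(Fp - cf$forces))
      fl <- c(fl, as.vector(cf$forces))
    }
  }
  out <- list(
    energy_rmse = if (length(de)) sqrt(mean(de^2)) else NA_real_,
    force_rmse = if (length(df)) sqrt(mean(df^2)) else NA_real_,
    force_rms_label = if (length(fl)) sqrt(mean(fl^2)) else NA_real_
  )
  out$force_rmse_relative <- out$force_rmse / out$force_rms_label
  out
}
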