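# Ordinary and generalized Clebsch-Gordan coupling in the real basis.
#
# Complex CG coefficients come from the Racah closed form; they are then
# transformed to the package's real spherical-harmonic basis.  Generalized
# coupling uses a sequential left-to-right binary tree over the input degrees,
# with the coupling-path index eta enumerating the admissible intermediate
# degrees in lexicographic order.

lfact <- function(n) lgamma(n + 1)

# Complex <l1 m1 l2 m2 | L M> (Condon-Shortley), array [2l1+1, 2l2+1, 2L+1].
cg_complex <- function(l1, l2, L) {
  d1 <- 2 * l1 + 1; d2 <- 2 * l2 + 1; dL <- 2 * L + 1
  out <- array(0, c(d1, d2, dL))
  if (L < abs(l1 - l2) || L > l1 + l2) return(out)
  pref_delta <- 0.5 * (lfact(l1 + l2 - L) + lfact(l1 - l2 + L) +
                         lfact(-l1 + l2 + L) - lfact(l1 + l2 + L + 1))
  for (m1 in -l1:l1) {
    for (m2 in -l2:l2) {
      M <- m1 + m2
      if (abs(M) > L) next
      pref <- 0.5 * (log(2 * L + 1) + lfact(l1 + m1) + lfact(l1 - m1) +
                       lfact(l2 + m2) + lfact(l2 - m2) +
                       lfact(L + M) + lfact(L - M)) + pref_delta
      kmin <- max(0, l2 - L - m1, l1 - L + m2)
      kmax <- min(l1 + l2 - L, l1 - m1, l2 + m2)
      if (kmin > kmax) next
      s <- 0
      for (k in kmin:kmax) {
        lg <- lfact(k) + lfact(l1 + l2 - L - k) + lfact(l1 - m1 - k) +
          lfact(l2 + m2 - k) + lfact(L - l2 + m1 + k) + lfact(L - l1 - m2 + k)
        s <- s + (-1)^k * exp(pref - lg)
      }
      out[m1 + l1 + 1, m2 + l2 + 1, M + L + 1] <- s
    }
  }
  out
}

# Unitary map from complex (Condon-Shortley) to real spherical harmonics:
# Y_real = U %*% Y_complex.  Rows/cols ordered m = -l..l.
real_transform <- function(l) {
  d <- 2 * l + 1
  U <- matrix(0 + 0i, d, d)
  U[l + 1, l + 1] <- 1
  if (l >= 1) {
    for (m in 1:l) {
      U[l + 1 + m, l + 1 + m] <- (-1)^m / sqrt(2)
      U[l + 1 + m, l + 1 - m] <- 1 / sqrt(2)
      U[l + 1 - m, l + 1 + m] <- -1i * (-1)^m / sqrt(2)
      U[l + 1 - m, l + 1 - m] <- 1i / sqrt(2)
    }
  }
  U
}

# Real-basis CG tensor, orthonormal in (m1, m2) for each M:
# sum_{m1 m2} C[m1,m2,M] C[m1,m2,M'] = delta_{M M'}.
cg_real_ortho <- function(l1, l2, L) {
  key <- paste("cgo", l1, l2, L, sep = "_")
  cached <- cache_get(key)
  if (!is.null(cached)) return(cached)
  Cc <- cg_complex(l1, l2, L)
  if (all(Cc == 0)) {
    out <- array(0, dim(Cc))
    cache_set(key, out)
    return(out)
  }
  U1 <- real_transform(l1); U2 <- real_transform(l2); UL <- real_transform(L)
  d1 <- 2 * l1 + 1; d2 <- 2 * l2 + 1; dL <- 2 * L + 1
  # Real inputs x^r relate to complex ones by x^c = U^H x^r, the coupled
  # output by v^r = U_L v^c, giving T = (conj(U1) x conj(U2)) C UL^T.
  Cm <- matrix(Cc, d1 * d2, dL)
  mid <- kronecker(Conj(U2), Conj(U1)) %*% Cm %*% t(UL)  # vec: m1 fastest
  Tm <- array(mid, c(d1, d2, dL))
  # The result is purely real (l1+l2+L even) or purely imaginary (odd);
  # fix the global phase so coefficients are real.
  if (max(abs(Im(Tm))) > max(abs(Re(Tm)))) Tm <- Tm * (0 - 1i)
  resid <- max(abs(Im(Tm)))
  if (resid > 1e-10) {
    stop("internal error: real CG tensor has mixed phase (", format(resid), ")")
  }
  out <- Re(Tm)
  # Deterministic sign: first entry with |.| > 1e-12 made positive.
  nz <- which(abs(out) > 1e-12)
  if (length(nz) && out[nz[1]] < 0) out <- -out
  cache_set(key, out)
  out
}

#' Ordinary Clebsch-Gordan coupling tensor (real basis)
#'
#' Returns the tensor coupling degrees `l1` and `l2` to degree `L` in the real
#' spherical-harmonic basis, normalized so the flattened tensor has unit
#' Frobenius norm.  The all-zero tensor is returned when the triangle rule
#' `|l1 - l2| <= L <= l1 + l2` fails.
#'
#' @param l1,l2,L non-negative integer degrees.
#' @return array of shape `(2*l1+1, 2*l2+1, 2*L+1)`.
#' @export
clebsch_gordan <- function(l1, l2, L) {
  stopifnot(l1 >= 0, l2 >= 0, L >= 0)
  C <- cg_real_ortho(l1, l2, L)
  if (all(C == 0)) return(C)
  C / sqrt(sum(C^2))
}

#' Enumerate sequential coupling schemes
#'
#' Couples `degrees` left to right; a scheme is the tuple of intermediate
#' degrees after each pairwise coupling (the last one equals `L`).  Schemes are
#' ordered lexicographically over the intermediates, which defines the path
#' index eta.
#'
#' @param degrees integer vector of input degrees (length nu >= 1).
#' @param L target degree.
#' @return list of integer vectors (intermediates including the final `L`);
#'   empty list when no admissible path exists.
#' @export
coupling_schemes <- function(degrees, L) {
  nu <- length(degrees)
  stopifnot(nu >= 1)
  if (nu == 1) {
    return(if (degrees[1] == L) list(integer(0)) else list())
  }
  paths <- list()
  # inter collects intermediates after couplings 2..nu; the final must be L.
  recurse2 <- function(current, idx, inter) {
    if (idx > nu) {
      if (current == L) paths[[length(paths) + 1]] <<- inter
      return(invisible(NULL))
    }
    l_next <- degrees[idx]
    for (t in abs(current - l_next):(current + l_next)) {
      recurse2(t, idx + 1, c(inter, t))
    }
  }
  recurse2(degrees[1], 2L, integer(0))
  paths
}

#' Generalized Clebsch-Gordan coupling with path enumeration
#'
#' Builds one coefficient tensor per coupling path eta for coupling `nu` input
#' degrees to target degree `L` (sequential left-to-right binary tree).  Under
#' the full orthogonal group a path is admissible only when the requested
#' `parity` matches the product of the inputs' spherical-harmonic parities,
#' `(-1)^sum(degrees)`; otherwise the result is empty.  Path tensors follow the
#' orthonormal convention `sum_v C[eta, v, LM] C[eta', v, LM'] =
#' delta(eta, eta') delta(M, M')`, so the single nu = 1 path is exactly the
#' identity on m and nu = 2 paths carry standard Clebsch-Gordan table values
#' (for L = 0 this coincides with the unit-Frobenius normalization of
#' [clebsch_gordan()]; for L > 0 the two differ by `sqrt(2L+1)`).  Distinct
#' paths are mutually orthogonal and linearly independent.  Results are cached
#' keyed by `(degrees, L, parity)`.
#'
#' @param degrees integer vector (l_1, ..., l_nu), nu >= 1.
#' @param L target degree.
#' @param parity +1 or -1; defaults to the natural parity `(-1)^L`.
#' @return object of class `coupling_coefficients`: list with `degrees`, `L`,
#'   `parity`, `schemes` (intermediate tuples) and `tensors` (list of arrays of
#'   shape `(2l_1+1, ..., 2l_nu+1, 2L+1)`).
#' @export
generalized_coupling <- function(degrees, L, parity = (-1)^L) {
  nu <- length(degrees)
  stopifnot(nu >= 1, all(degrees >= 0), L >= 0, parity %in% c(-1, 1))
  key <- paste("gc", paste(degrees, collapse = "."), L, parity, sep = "_")
  cached <- cache_get(key)
  if (!is.null(cached)) return(cached)
  natural <- (-1)^sum(degrees)
  if (parity != natural) {
    out <- new_coupling(degrees, L, parity, list(), list())
    cache_set(key, out)
    return(out)
  }
  schemes <- coupling_schemes(degrees, L)
  tensors <- lapply(schemes, function(inter) {
    dims <- 2 * degrees + 1
    if (nu == 1) {
      G <- diag(2 * L + 1)
      dim(G) <- c(dims, 2 * L + 1)
      return(G)
    }
    seqs <- c(inter)
    G <- cg_real_ortho(degrees[1], degrees[2], seqs[1])
    if (nu > 2) {
      for (step in 3:nu) {
        t_prev <- seqs[step - 2]
        t_new <- seqs[step - 1]
        Cstep <- cg_real_ortho(t_prev, degrees[step], t_new)
        dG <- dim(G)
        lead <- prod(dG[-length(dG)])
        Gm <- matrix(G, lead, dG[length(dG)])
        Cm <- matrix(Cstep, dim(Cstep)[1], dim(Cstep)[2] * dim(Cstep)[3])
        G <- Gm %*% Cm
        dim(G) <- c(dG[-length(dG)], dim(Cstep)[2], dim(Cstep)[3])
      }
    }
    G
  })
  out <- new_coupling(degrees, L, parity, schemes, tensors)
  cache_set(key, out)
  out
}

new_coupling <- function(degrees, L, parity, schemes, tensors) {
  structure(
    list(degrees = as.integer(degrees), L = as.integer(L),
         parity = as.integer(parity), schemes = schemes, tensors = tensors),
    class = "coupling_coefficients"
  )
}

#' @export
print.coupling_coefficients <- function(x, ...) {
  cat("coupling_coefficients: degrees (", paste(x$degrees, collapse = ", "),
      ") -> L =", x$L, ", parity", x$parity,
      ";", length(x$tensors), "path(s)\n")
  invisible(x)
}

# ---- coefficient cache ------------------------------------------------------
# In-memory cache always; optional versioned on-disk layer under
# options(equiace.cache_dir = <dir>) with layout <dir>/v1/<key>.rds.

.equiace_cache <- new.env(parent = emptyenv())

cache_get <- function(key) {
  if (exists(key, envir = .equiace_cache, inherits = FALSE)) {
    return(get(key, envir = .equiace_cache))
  }
  dir <- getOption("equiace.cache_dir", NULL)
  if (!is.null(dir)) {
    f <- file.path(dir, "v1", paste0(key, ".rds"))
    if (file.exists(f)) {
      val <- readRDS(f)
      assign(key, val, envir = .equiace_cache)
      return(val)
    }
  }
  NULL
}

cache_set <- function(key, value) {
  assign(key, value, envir = .equiace_cache)
  dir <- getOption("equiace.cache_dir", NULL)
  if (!is.null(dir)) {
    sub <- file.path(dir, "v1")
    if (!dir.exists(sub)) dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    saveRDS(value, file.path(sub, paste0(key, ".rds")))
  }
  invisible(value)
}
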