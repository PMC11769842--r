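# Real spherical harmonics.
#
# Convention: orthonormal real basis without the Condon-Shortley phase,
# components ordered m = -l..+l.  Negative m carry sin(m*phi), positive m
# cos(m*phi), so that Y_1 is proportional to (y, z, x).  Everything is
# evaluated through real polynomial recursions in the Cartesian components,
# which keeps the code valid for complex-step differentiation.

# Vectorized evaluation on unit direction rows X (n x 3, possibly complex).
# Returns [n, (lmax+1)^2]; columns blocked by l, m = -l..l within a block.
sh_matrix <- function(X, lmax) {
  n <- nrow(X)
  x <- X[, 1]; y <- X[, 2]; z <- X[, 3]
  zero <- x * 0
  out <- matrix(zero[1], n, (lmax + 1)^2)
  if (is.complex(x) || is.complex(y) || is.complex(z)) out <- out + 0i

  # C_m = s^m cos(m phi), S_m = s^m sin(m phi) as polynomials in (x, y).
  C <- vector("list", lmax + 1)
  S <- vector("list", lmax + 1)
  C[[1]] <- zero + 1
  S[[1]] <- zero
  if (lmax >= 1) {
    for (m in 1:lmax) {
      C[[m + 1]] <- x * C[[m]] - y * S[[m]]
      S[[m + 1]] <- x * S[[m]] + y * C[[m]]
    }
  }

  # Q[l, m] = P_l^m(z) / s^m, a polynomial in z (no Condon-Shortley phase).
  Q <- vector("list", lmax + 1)
  for (l in 0:lmax) Q[[l + 1]] <- vector("list", l + 1)
  Q[[1]][[1]] <- zero + 1
  if (lmax >= 1) {
    for (m in 0:lmax) {
      if (m > 0) {
        Q[[m + 1]][[m + 1]] <- Q[[m]][[m]] * (2 * m - 1)    # (2m-1)!! step
      }
      if (m + 1 <= lmax) {
        Q[[m + 2]][[m + 1]] <- z * (2 * m + 1) * Q[[m + 1]][[m + 1]]
      }
      if (m + 2 <= lmax) {
        for (l in (m + 2):lmax) {
          Q[[l + 1]][[m + 1]] <- ((2 * l - 1) * z * Q[[l]][[m + 1]] -
                                    (l - 1 + m) * Q[[l - 1]][[m + 1]]) / (l - m)
        }
      }
    }
  }

  for (l in 0:lmax) {
    base <- l^2
    # m = 0
    N0 <- sqrt((2 * l + 1) / (4 * pi))
    out[, base + l + 1] <- N0 * Q[[l + 1]][[1]]
    if (l >= 1) {
      for (m in 1:l) {
        Nm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
        v <- sqrt(2) * Nm * Q[[l + 1]][[m + 1]]
        out[, base + l + 1 + m] <- v * C[[m + 1]]   # +m ~ cos(m phi)
        out[, base + l + 1 - m] <- v * S[[m + 1]]   # -m ~ sin(m phi)
      }
    }
  }
  out
}

# Column indices of degree l inside an sh_matrix for a given lmax.
sh_cols <- function(l) (l^2 + 1):((l + 1)^2)

#' Real spherical harmonics of a unit direction
#'
#' Evaluates the orthonormal real spherical harmonics (no Condon-Shortley
#' phase) for all degrees `0 <= l <= l_max`.  Components within a degree are
#' ordered `m = -l..+l`; negative `m` carry the `sin(m phi)` combinations, so
#' the degree-1 block is proportional to `(y, z, x)`.
#'
#' @param direction unit 3-vector (checked to norm 1 within 1e-8).
#' @param l_max maximum degree, >= 0.
#' @return list of length `l_max + 1`; element `l + 1` is the numeric vector of
#'   the `2l + 1` degree-`l` components.
#' @examples
#' spherical_harmonics(c(0, 0, 1), 1)
#' @export
spherical_harmonics <- function(direction, l_max) {
  direction <- as.numeric(direction)
  if (length(direction) != 3L || !all(is.finite(direction))) {
    stop("spherical_harmonics: direction must be a finite 3-vector")
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("spherical_harmonics: zero vector has no direction")
  if (abs(nrm - 1) > 1e-8) {
    stop("spherical_harmonics: direction must be a unit vector (|v| = ",
         format(nrm), ")")
  }
  if (l_max < 0) stop("spherical_harmonics: l_max must be >= 0")
  Y <- sh_matrix(matrix(direction, 1, 3), l_max)
  lapply(0:l_max, function(l) as.numeric(Y[1, sh_cols(l)]))
}
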