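# Real Wigner-D matrices.
#
# D^1 is the 3x3 rotation matrix itself re-expressed in the (y, z, x) ordering
# of the real degree-1 harmonics.  Higher degrees are built recursively by
# Clebsch-Gordan projection of D^(L-1) (x) D^1, which reproduces exactly the
# representation under which sh_matrix() features transform.

# Representation matrix of an arbitrary orthogonal Q (proper or improper) on
# spherical-harmonic-type (parity (-1)^L) degree-L features.
wigner_rotation <- function(Q, L) {
  if (L == 0) return(matrix(1, 1, 1))
  perm <- c(2L, 3L, 1L)           # (m=-1,0,+1) ~ (y, z, x)
  D1 <- Q[perm, perm, drop = FALSE]
  if (L == 1) return(D1)
  D <- D1
  for (l in 2:L) {
    C <- cg_real_ortho(l - 1, 1, l)         # [(2l-1) x 3 x (2l+1)]
    dprev <- 2 * l - 1
    Cm <- matrix(C, dprev * 3, 2 * l + 1)   # vec index: m_prev fastest
    big <- kronecker(D1, D)                 # matches vec(m_prev fastest)
    D <- t(Cm) %*% big %*% Cm
  }
  D
}

#' Real Wigner-D matrix
#'
#' Representation matrix of an orthogonal operation on a degree-`L` feature
#' block in the package's real basis.  For proper rotations this is the
#' degree-`L` rotation matrix; an improper operation `Q` acting on a feature of
#' parity `p` is represented as `p * D(-Q)` (with `-Q` proper), so
#' spherical-harmonic features (parity `(-1)^L`) transform exactly as
#' `sh_matrix` values do.
#'
#' @param rotation a `rotation_operation` or a plain orthogonal 3x3 matrix.
#' @param L degree, >= 0.
#' @param parity +1 or -1 parity label of the feature; default natural parity
#'   `(-1)^L`.
#' @return orthogonal `(2L+1) x (2L+1)` matrix.
#' @export
wigner_D <- function(rotation, L, parity = (-1)^L) {
  stopifnot(L >= 0, parity %in% c(-1, 1))
  rot <- as_rotation(rotation)
  Q <- rot$matrix
  if (!rot$improper) return(wigner_rotation(Q, L))
  parity * wigner_rotation(-Q, L)
}
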