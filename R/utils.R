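# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded library internals never
#' perturb the caller's random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Uniform random rotation matrices
#'
#' Samples rotations Haar-uniformly on SO(3) via normalized quaternions.
#' @param n number of rotations.
#' @param seed integer seed.
#' @return list of 3x3 orthogonal matrices with determinant +1.
#' @export
random_rotations <- function(n, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      q <- stats::rnorm(4)
      q <- q / sqrt(sum(q^2))
      quaternion_to_matrix(q)
    })
  })
}

quaternion_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Construct a rotation (or roto-reflection) operation
#'
#' @param matrix 3x3 real orthogonal matrix.
#' @return object of class `rotation_operation` with fields `matrix` and
#'   `improper` (TRUE iff det = -1).
#' @export
rotation_operation <- function(matrix) {
  matrix <- as.matrix(matrix)
  stopifnot(all(dim(matrix) == c(3L, 3L)))
  dev <- max(abs(crossprod(matrix) - diag(3)))
  if (dev > 1e-12) {
    stop("rotation_operation: matrix is not orthogonal (deviation ", format(dev), ")")
  }
  d <- det(matrix)
  structure(list(matrix = matrix, improper = d < 0), class = "rotation_operation")
}

as_rotation <- function(Q) {
  if (inherits(Q, "rotation_operation")) Q else rotation_operation(Q)
}

# Dense pooling matrix mapping edge values to receiver atoms; complex-safe
# because the aggregation is a plain matrix product.
pooling_matrix <- function(receivers, n_atoms) {
  P <- matrix(0, n_atoms, length(receivers))
  if (length(receivers)) P[cbind(receivers, seq_along(receivers))] <- 1
  P
}

# Contract the trailing index of an array with a matrix:
# out[..., b] = sum_a x[..., a] M[a, b].  Used for CG contractions.
contract_last <- function(x, M) {
  d <- dim(x)
  k <- length(d)
  y <- matrix(x, prod(d[-k]), d[k]) %*% M
  dim(y) <- c(d[-k], ncol(M))
  y
}

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch).
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}

#' Quadrature grid on the unit sphere
#'
#' Gauss-Legendre in cos(theta) crossed with a uniform trapezoid in phi;
#' exact for spherical polynomials up to the grid's band limit.
#' @param n_theta polar nodes; @param n_phi azimuthal nodes.
#' @return list with `points` (n x 3 unit vectors) and `weights` summing to 4*pi.
#' @keywords internal
#' @noRd
sphere_quadrature <- function(n_theta, n_phi) {
  gl <- gauss_legendre(n_theta)
  ct <- gl$nodes
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  pts <- cbind(
    as.vector(outer(st, cos(phi))),
    as.vector(outer(st, sin(phi))),
    rep(ct, times = n_phi)
  )
  w <- rep(gl$weights, times = n_phi) * (2 * pi / n_phi)
  list(points = pts, weights = w)
}

# Complex-safe norm of rows of an n x 3 matrix (no abs()).
row_norms <- function(x) {
  sqrt(x[, 1]^2 + x[, 2]^2 + x[, 3]^2)
}

is_complexish <- function(x) is.complex(x)

# Imaginary unit step used for complex-step differentiation.
CSTEP <- 1e-100
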