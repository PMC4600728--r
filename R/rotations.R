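# Small rotation-matrix toolkit. Rotations act on column vectors: y = R %*% x.

#' Rotation matrix from axis and angle
#'
#' @param axis Numeric length-3 axis (need not be normalized).
#' @param angle Rotation angle in radians.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  stopifnot(length(axis) == 3, is.finite(angle))
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero", call. = FALSE)
  rotvec_to_matrix(axis / n * angle)
}

#' Rotation matrix from a rotation vector (exponential map)
#'
#' Rodrigues formula: the rotation vector's direction is the axis, its norm the
#' angle in radians.
#'
#' @param r Numeric length-3 rotation vector (radians).
#' @return 3x3 proper rotation matrix.
#' @export
rotvec_to_matrix <- function(r) {
  stopifnot(length(r) == 3, all(is.finite(r)))
  theta <- sqrt(sum(r^2))
  if (theta < 1e-14) return(diag(3))
  k <- r / theta
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  # atan2 form: full precision near 0 and pi, unlike acos of the trace
  s <- sqrt((R[3, 2] - R[2, 3])^2 + (R[1, 3] - R[3, 1])^2 +
              (R[2, 1] - R[1, 2])^2) / 2
  c <- (sum(diag(R)) - 1) / 2
  atan2(s, c)
}

#' Check that a matrix is a proper rotation
#'
#' @param R 3x3 matrix.
#' @param tol Tolerance on orthonormality and determinant.
#' @return Logical scalar.
#' @export
is_rotation_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol &&
    abs(det(R) - 1) < tol
}

# angle between two rotations (geodesic distance on SO(3))
rotation_distance <- function(R1, R2) rotation_angle(crossprod(R1, R2))

#' Rank-2 rotation character
#'
#' \eqn{\chi_2(\theta) = 1 + 2\cos\theta + 2\cos 2\theta}, the character of the
#' l = 2 irreducible representation of SO(3). The isotropic average of
#' \eqn{P_2(u \cdot R u)} over unit vectors u equals \eqn{\chi_2(\theta)/5}
#' for a rotation R by angle \eqn{\theta}.
#'
#' @param theta Rotation angle(s), radians.
#' @return Character value(s).
#' @export
chi2_character <- function(theta) 1 + 2 * cos(theta) + 2 * cos(2 * theta)

#' Quasi-uniform unit vectors on the sphere
#'
#' Deterministic, seed-free generalized-spiral (Fibonacci lattice) construction.
#' For `n = 1` the conventional single vector (0, 0, 1) is returned.
#'
#' @param n Number of vectors (>= 1).
#' @return `n x 3` matrix of unit row vectors.
#' @export
#' @examples
#' u <- sphere_vectors(100)
#' eigen(crossprod(u) / 100)$values # all close to 1/3
sphere_vectors <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Quasi-uniform grid of rotations (powder/orientation average)
#'
#' Deterministic quasi-uniform sampling of SO(3): axes from a spherical
#' Fibonacci lattice combined with golden-angle stepped twist angles. Used for
#' powder averaging in the numerical relaxation model.
#'
#' @param n Number of rotations.
#' @return List of 3x3 rotation matrices, equal weights implied.
#' @export
rotation_grid <- function(n) {
  stopifnot(n >= 1)
  axes <- sphere_vectors(n)
  ga <- pi * (3 - sqrt(5))
  lapply(seq_len(n), function(i) {
    # twist about z first, then tilt z onto the Fibonacci axis
    a <- axes[i, ]
    b <- acos(min(1, max(-1, a[3])))
    al <- atan2(a[2], a[1])
    Rz <- rotation_about_axis(c(0, 0, 1), (i - 1) * ga)
    rotation_about_axis(c(0, 0, 1), al) %*%
      rotation_about_axis(c(0, 1, 0), b) %*% Rz
  })
}
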