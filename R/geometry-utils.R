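# Rigid-transform helpers shared by the sweep generator and the
# reconstruction code. Rotations are 3x3 orthonormal matrices internally;
# unit quaternions (w, x, y, z) are accepted and used for JSON interchange.

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q Numeric length-4 vector `(w, x, y, z)`; normalised internally.
#' @return A 3x3 orthonormal rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  stopifnot(is.numeric(q), length(q) == 4)
  n <- sqrt(sum(q^2))
  if (n == 0) stop("quaternion has zero norm")
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Returns the quaternion with non-negative scalar part.
#'
#' @param R A 3x3 orthonormal rotation matrix.
#' @return Numeric length-4 vector `(w, x, y, z)`.
#' @export
rotmat_to_quat <- function(R) {
  check_rotation(R)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

# Small-angle rotation from an axis-angle vector (radians).
rotvec_to_rotmat <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < .Machine$double.eps) return(diag(3))
  k <- v / theta
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

check_rotation <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3))) {
    stop("rotation must be a 3x3 matrix")
  }
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("rotation matrix is not orthonormal (tolerance 1e-6)")
  }
  invisible(R)
}

as_rotmat <- function(rotation) {
  if (is.numeric(rotation) && length(rotation) == 4) {
    quat_to_rotmat(rotation)
  } else {
    check_rotation(rotation)
    rotation
  }
}
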