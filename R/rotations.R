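#' Convert intrinsic Z-X-Z Euler angles to a rotation matrix
#'
#' Orientations follow the Dynamo-style intrinsic Z-X-Z convention used
#' throughout the package: `R = Rz(rot) %*% Rx(tilt) %*% Rz(psi)`, angles in
#' degrees. The columns of the matrix are the particle's x, y and z axes
#' expressed in world coordinates.
#'
#' @param rot_deg,tilt_deg,psi_deg Euler angles in degrees (scalars).
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @seealso [matrix_to_euler()]
#' @export
#' @examples
#' euler_to_matrix(30, 45, 60)
euler_to_matrix <- function(rot_deg, tilt_deg, psi_deg) {
  c1 <- cos(deg2rad(rot_deg));  s1 <- sin(deg2rad(rot_deg))
  c2 <- cos(deg2rad(tilt_deg)); s2 <- sin(deg2rad(tilt_deg))
  c3 <- cos(deg2rad(psi_deg));  s3 <- sin(deg2rad(psi_deg))
  matrix(c(
    c1 * c3 - s1 * c2 * s3, -c1 * s3 - s1 * c2 * c3,  s1 * s2,
    s1 * c3 + c1 * c2 * s3, -s1 * s3 + c1 * c2 * c3, -c1 * s2,
    s2 * s3,                 s2 * c3,                 c2
  ), nrow = 3, byrow = TRUE)
}

#' Recover intrinsic Z-X-Z Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()]. For gimbal-degenerate rotations
#' (tilt = 0 or 180 degrees) the convention `psi = 0` is used, so round
#' trips reproduce the rotation (not necessarily the original triplet).
#'
#' @param R A 3x3 orthonormal rotation matrix.
#' @return Named numeric vector `c(rot_deg, tilt_deg, psi_deg)`.
#' @export
matrix_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  c2 <- max(-1, min(1, R[3, 3]))
  tilt <- acos(c2)
  if (abs(sin(tilt)) > 1e-10) {
    rot <- atan2(R[1, 3], -R[2, 3])
    psi <- atan2(R[3, 1],  R[3, 2])
  } else {
    # tilt ~ 0 or pi: only rot +/- psi is defined; put it all in rot
    psi <- 0
    rot <- if (c2 > 0) atan2(R[2, 1], R[1, 1]) else atan2(-R[2, 1], R[1, 1])
  }
  c(rot_deg = rad2deg(rot), tilt_deg = rad2deg(tilt), psi_deg = rad2deg(psi))
}

# rotation matrices from vectorised euler columns -> list of matrices
euler_rows_to_matrices <- function(rot, tilt, psi) {
  purrr::pmap(list(rot, tilt, psi), euler_to_matrix)
}

# orientation matrix from orthonormal axes given as rows of 3-vectors
axes_to_euler <- function(xhat, yhat, zhat) {
  n <- nrow(xhat)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    out[i, ] <- matrix_to_euler(cbind(xhat[i, ], yhat[i, ], zhat[i, ]))
  }
  colnames(out) <- c("rot_deg", "tilt_deg", "psi_deg")
  out
}

# rotation of `angle_rad` about unit axis `u` (Rodrigues)
rotation_about_axis <- function(u, angle_rad) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

is_rotation_matrix <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}
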