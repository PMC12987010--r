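# Quaternions as (w, x, y, z) rows. Head orientation comes in as intrinsic
# Tait-Bryan angles (degrees): yaw about +Y, then pitch about +X, then roll
# about +Z (left-handed display convention, forward = +Z).

euler_to_quat <- function(pitch_deg, yaw_deg, roll_deg) {
  hp <- pitch_deg * pi / 360; hy <- yaw_deg * pi / 360; hr <- roll_deg * pi / 360
  qy <- cbind(cos(hy), 0, sin(hy), 0)
  qx <- cbind(cos(hp), sin(hp), 0, 0)
  qz <- cbind(cos(hr), 0, 0, sin(hr))
  quat_mult(quat_mult(qy, qx), qz)
}

quat_mult <- function(a, b) {
  cbind(a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
        a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
        a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
        a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1])
}

quat_conj <- function(q) cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])

# Rotate the forward vector (0, 0, 1) by each quaternion row.
quat_forward <- function(q) {
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  cbind(2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2))
}

# Chordal mean rotation: sign-align quaternions to the first frame, average
# component-wise, renormalize. Adequate for the small intra-window rotations
# of seated head motion.
quat_mean <- function(q) {
  s <- sign(q %*% q[1, ])
  s[s == 0] <- 1
  qm <- colMeans(q * as.vector(s))
  nrm <- sqrt(sum(qm^2))
  if (nrm < 1e-9) stopf("degenerate orientation data")
  matrix(qm / nrm, 1)
}

#' Head direction signals relative to the window-average orientation
#'
#' Computes the window-average rotation (chordal quaternion mean), applies
#' each frame's rotation relative to that mean to the forward vector
#' (0, 0, 1), and converts the resulting direction to spherical angles
#' phi_yaw / phi_pitch via [gaze_angles()]. A constant orientation therefore
#' maps to identically zero angles.
#'
#' @param rot numeric matrix (frames x 3) of head rotation angles in degrees,
#'   columns pitch, yaw, roll.
#' @return list with `yaw`, `pitch` (degrees) and `dir` (frames x 3).
#' @export
head_direction_signals <- function(rot) {
  keep <- stats::complete.cases(rot)
  if (sum(keep) < 2L) stopf("degenerate orientation data")
  q <- euler_to_quat(rot[, 1L], rot[, 2L], rot[, 3L])
  qbar <- quat_mean(q[keep, , drop = FALSE])
  rel <- quat_mult(matrix(quat_conj(qbar), nrow(q), 4, byrow = TRUE), q)
  dir <- quat_forward(rel)
  ang <- gaze_angles(dir)
  list(yaw = ang$yaw, pitch = ang$pitch, dir = dir)
}
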