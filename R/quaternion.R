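# Minimal unit-quaternion algebra for AHRS orientation streams.
#
# Quaternions are stored as length-4 numeric vectors or n x 4 matrices in
# (w, x, y, z) order, scalar first. Euler angles follow the intrinsic Z-Y-X
# (yaw-pitch-roll) convention customary for AHRS output, with the z axis
# vertical: yaw rotates about vertical, then pitch about the once-rotated y,
# then roll about the twice-rotated x.

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4, byrow = TRUE)
  if (ncol(q) != 4) stop("quaternions need 4 components (w, x, y, z)",
                         call. = FALSE)
  q
}

#' Normalize quaternions to unit norm
#'
#' @param q A length-4 vector or n x 4 matrix, (w, x, y, z).
#' @return Object of the same shape with unit rows.
#' @export
quat_normalize <- function(q) {
  qm <- as_quat_matrix(q)
  n <- sqrt(rowSums(qm^2))
  if (any(n < 1e-12)) stop("zero-norm quaternion", call. = FALSE)
  out <- qm / n
  if (is.null(dim(q))) out[1, ] else out
}

#' Quaternion conjugate
#' @inheritParams quat_normalize
#' @return Same shape as `q`.
#' @export
quat_conjugate <- function(q) {
  qm <- as_quat_matrix(q)
  out <- cbind(qm[, 1], -qm[, 2], -qm[, 3], -qm[, 4])
  if (is.null(dim(q))) out[1, ] else out
}

#' Hamilton product of quaternions
#'
#' Row-wise product `a * b`; rows are recycled if one argument has a single
#' row.
#' @param a,b Quaternions as vectors or n x 4 matrices, (w, x, y, z).
#' @return n x 4 matrix (or length-4 vector if both inputs were vectors).
#' @export
quat_multiply <- function(a, b) {
  am <- as_quat_matrix(a); bm <- as_quat_matrix(b)
  n <- max(nrow(am), nrow(bm))
  if (nrow(am) == 1) am <- am[rep(1, n), , drop = FALSE]
  if (nrow(bm) == 1) bm <- bm[rep(1, n), , drop = FALSE]
  w <- am[, 1] * bm[, 1] - am[, 2] * bm[, 2] - am[, 3] * bm[, 3] - am[, 4] * bm[, 4]
  x <- am[, 1] * bm[, 2] + am[, 2] * bm[, 1] + am[, 3] * bm[, 4] - am[, 4] * bm[, 3]
  y <- am[, 1] * bm[, 3] - am[, 2] * bm[, 4] + am[, 3] * bm[, 1] + am[, 4] * bm[, 2]
  z <- am[, 1] * bm[, 4] + am[, 2] * bm[, 3] - am[, 3] * bm[, 2] + am[, 4] * bm[, 1]
  out <- cbind(w, x, y, z)
  dimnames(out) <- NULL
  if (is.null(dim(a)) && is.null(dim(b))) out[1, ] else out
}

#' Rotation matrix of a unit quaternion
#' @param q A single quaternion (w, x, y, z).
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(as.numeric(q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion from intrinsic Z-Y-X Euler angles
#'
#' @param yaw,pitch,roll Angles in degrees (vectors recycle).
#' @return n x 4 quaternion matrix (length-4 vector for scalar input).
#' @export
quat_from_euler <- function(yaw, pitch, roll = 0) {
  n <- max(length(yaw), length(pitch), length(roll))
  yaw <- rep_len(deg2rad(yaw), n) / 2
  pitch <- rep_len(deg2rad(pitch), n) / 2
  roll <- rep_len(deg2rad(roll), n) / 2
  cy <- cos(yaw); sy <- sin(yaw)
  cp <- cos(pitch); sp <- sin(pitch)
  cr <- cos(roll); sr <- sin(roll)
  out <- cbind(
    cy * cp * cr + sy * sp * sr,
    cy * cp * sr - sy * sp * cr,
    cy * sp * cr + sy * cp * sr,
    sy * cp * cr - cy * sp * sr
  )
  dimnames(out) <- NULL
  if (n == 1) out[1, ] else out
}

#' Intrinsic Z-Y-X Euler angles of quaternions
#'
#' @param q A quaternion vector or n x 4 matrix, (w, x, y, z).
#' @return Data frame with columns `yaw`, `pitch`, `roll` in degrees;
#'   yaw/roll in (-180, 180], pitch in [-90, 90].
#' @export
quat_to_euler <- function(q) {
  qm <- quat_normalize(as_quat_matrix(q))
  w <- qm[, 1]; x <- qm[, 2]; y <- qm[, 3]; z <- qm[, 4]
  yaw <- atan2(2 * (x * y + w * z), 1 - 2 * (y^2 + z^2))
  s <- 2 * (w * y - x * z)
  pitch <- asin(pmax(-1, pmin(1, s)))
  roll <- atan2(2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  data.frame(yaw = rad2deg(yaw), pitch = rad2deg(pitch), roll = rad2deg(roll))
}

#' Apply a small random rotation to quaternions
#'
#' Used by the synthetic-data generator to model orientation noise: each row
#' is left-multiplied by a rotation about a random axis with a normally
#' distributed angle.
#'
#' @param q n x 4 quaternion matrix.
#' @param sd_deg Standard deviation of the perturbing rotation angle, degrees.
#' @return Perturbed n x 4 unit-quaternion matrix.
#' @export
quat_jitter <- function(q, sd_deg) {
  qm <- as_quat_matrix(q)
  if (sd_deg <= 0) return(qm)
  n <- nrow(qm)
  ang <- deg2rad(rnorm(n, 0, sd_deg)) / 2
  ax <- matrix(rnorm(3 * n), ncol = 3)
  ax <- ax / sqrt(rowSums(ax^2))
  noise <- cbind(cos(ang), sin(ang) * ax)
  quat_normalize(quat_multiply(noise, qm))
}
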