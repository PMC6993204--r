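# Unit-quaternion helpers (w-first convention: columns w, x, y, z).
#
# Orientation enters the pipeline in two places: spherical linear
# interpolation during resampling, and the geodesic angle accumulation of the
# normalized angular path metric. Both need the double-cover fixed so that
# consecutive samples never take the long way around the 3-sphere.

quat_normalize <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  q / row_norms(q)
}

# Flip signs so that dot(q_n, q_{n+1}) >= 0 for all consecutive rows.
quat_fix_signs <- function(q) {
  if (nrow(q) < 2) return(q)
  sgn <- cumprod(c(1, ifelse(rowSums(q[-nrow(q), , drop = FALSE] *
                                     q[-1, , drop = FALSE]) < 0, -1, 1)))
  q * sgn
}

# Slerp between unit quaternions q1 and q2 at fractions u in [0, 1].
quat_slerp <- function(q1, q2, u) {
  d <- sum(q1 * q2)
  if (d < 0) { q2 <- -q2; d <- -d }
  d <- min(d, 1)
  if (d > 1 - 1e-10) {
    out <- outer(1 - u, q1) + outer(u, q2)   # lerp in the small-angle limit
    return(quat_normalize(out))
  }
  th <- acos(d)
  w1 <- sin((1 - u) * th) / sin(th)
  w2 <- sin(u * th) / sin(th)
  quat_normalize(outer(w1, q1) + outer(w2, q2))
}

# Geodesic rotation angle (rad) between consecutive rows of a quaternion
# matrix, insensitive to the double cover.
quat_step_angles <- function(q) {
  if (nrow(q) < 2) return(numeric(0))
  d <- abs(rowSums(q[-nrow(q), , drop = FALSE] * q[-1, , drop = FALSE]))
  2 * acos(clamp(d, -1, 1))
}

# Quaternion for a rotation of `angle` radians about unit `axis`.
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  cbind(cos(angle / 2),
        sin(angle / 2) * axis[1],
        sin(angle / 2) * axis[2],
        sin(angle / 2) * axis[3])
}

# Rotation matrix -> unit quaternion (w, x, y, z), Shepperd's method.
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# Hamilton product; q1, q2 are length-4 (w, x, y, z) or n x 4 matrices.
quat_multiply <- function(q1, q2) {
  if (is.null(dim(q1))) q1 <- matrix(q1, ncol = 4)
  if (is.null(dim(q2))) q2 <- matrix(q2, ncol = 4)
  if (nrow(q1) == 1 && nrow(q2) > 1) q1 <- q1[rep(1, nrow(q2)), ]
  if (nrow(q2) == 1 && nrow(q1) > 1) q2 <- q2[rep(1, nrow(q1)), ]
  cbind(q1[, 1] * q2[, 1] - q1[, 2] * q2[, 2] - q1[, 3] * q2[, 3] - q1[, 4] * q2[, 4],
        q1[, 1] * q2[, 2] + q1[, 2] * q2[, 1] + q1[, 3] * q2[, 4] - q1[, 4] * q2[, 3],
        q1[, 1] * q2[, 3] - q1[, 2] * q2[, 4] + q1[, 3] * q2[, 1] + q1[, 4] * q2[, 2],
        q1[, 1] * q2[, 4] + q1[, 2] * q2[, 3] - q1[, 3] * q2[, 2] + q1[, 4] * q2[, 1])
}

#' Rigidly transform a trial recording
#'
#' Applies a global rotation and translation to a trial: positions are
#' mapped to `R p + shift`, forces and torques are co-rotated, and
#' orientations are left-composed with the rotation. Used by the rigid-
#' motion invariance properties of the metric suite and by the synthetic
#' generator's tissue-pose handling.
#'
#' @param trial A [trial_recording()].
#' @param rotation 3 x 3 rotation matrix.
#' @param shift Translation 3-vector, m.
#' @return The transformed [trial_recording()].
#' @export
rigid_transform_trial <- function(trial, rotation = diag(3),
                                  shift = c(0, 0, 0)) {
  stopifnot(inherits(trial, "trial_recording"))
  trial$position <- sweep(trial$position %*% t(rotation), 2, shift, "+")
  trial$force <- trial$force %*% t(rotation)
  trial$torque <- trial$torque %*% t(rotation)
  qr_ <- quat_from_matrix(rotation)
  trial$quaternion <- quat_normalize(quat_multiply(qr_, trial$quaternion))
  for (ch in c("velocity", "acceleration", "jerk"))
    if (!is.null(trial[[ch]])) trial[[ch]] <- trial[[ch]] %*% t(rotation)
  trial
}
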