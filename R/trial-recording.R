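#' Construct a trial recording
#'
#' A `trial_recording` holds one trial's synchronized time series: tooltip
#' position, tooltip orientation (unit quaternion, w-first), gripper state,
#' tissue-interaction force and torque, plus trial metadata. All channels
#' share the time base `t`.
#'
#' @param t Timestamps, s, strictly increasing.
#' @param position N x 3 matrix of tooltip positions, m.
#' @param quaternion N x 4 matrix of unit quaternions (columns w, x, y, z).
#' @param gripper Length-N gripper state (angle-like scalar; closed when at
#'   or below the gripper threshold used by the segmentation stage).
#' @param force N x 3 matrix of tissue-interaction forces, N.
#' @param torque N x 3 matrix of tissue-interaction torques, N·m.
#' @param meta Named list of metadata: `participant`, `condition` (one of
#'   `"NF"`, `"PE"`, `"DF"`), `setup` (`"open"` or `"teleop"`), `phase`,
#'   `block`, `trial`, `rate` (native sampling rate, Hz). Missing entries are
#'   allowed.
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(t, position, quaternion, gripper, force, torque,
                            meta = list()) {
  t <- as.numeric(t)
  n <- length(t)
  position <- as.matrix(position); quaternion <- as.matrix(quaternion)
  force <- as.matrix(force); torque <- as.matrix(torque)
  gripper <- as.numeric(gripper)
  if (any(diff(t) <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  dims <- c(nrow(position), nrow(quaternion), length(gripper),
            nrow(force), nrow(torque))
  if (any(dims != n))
    stop("all channels must have the same length as `t`", call. = FALSE)
  if (ncol(position) != 3 || ncol(force) != 3 || ncol(torque) != 3)
    stop("position, force and torque must have 3 columns", call. = FALSE)
  if (ncol(quaternion) != 4)
    stop("quaternion must have 4 columns (w, x, y, z)", call. = FALSE)
  qn <- row_norms(quaternion)
  if (any(abs(qn - 1) > 1e-6))
    stop("quaternions must be unit-norm", call. = FALSE)
  quaternion <- quaternion / qn
  structure(list(t = t, position = unname(position),
                 quaternion = unname(quaternion), gripper = gripper,
                 force = unname(force), torque = unname(torque),
                 meta = meta),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  dur <- diff(range(x$t))
  rate <- x$meta$rate %||% (1 / stats::median(diff(x$t)))
  cat(sprintf("<trial_recording> %d samples, %.2f s, ~%.0f Hz%s\n",
              length(x$t), dur, rate,
              if (!is.null(x$meta$setup)) paste0(", ", x$meta$setup) else ""))
  derived <- intersect(c("velocity", "acceleration", "jerk"), names(x))
  if (length(derived))
    cat("  derived channels:", paste(derived, collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(trial) length(trial$t)

# TRUE when the time base is uniform to within `tol` of its median step.
is_uniform <- function(trial, tol = 1e-9) {
  dt <- diff(trial$t)
  length(dt) > 0 && (max(dt) - min(dt)) < tol
}

sample_rate <- function(trial) 1 / stats::median(diff(trial$t))
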