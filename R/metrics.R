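# Per-trial(-subtask) performance metrics: task performance, force,
# kinematic and motor-control-grounded classes.

# Resolve the sample indices (1-based) of a segment choice.
segment_indices <- function(seg, segment = "trial") {
  stopifnot(inherits(seg, "segmented_trial"))
  if (identical(segment, "trial"))
    return((seg$bounds[1] + 1L):(seg$bounds[2] + 1L))
  if (!segment %in% subtask_levels)
    stop(sprintf("unknown segment '%s'", segment), call. = FALSE)
  idx <- which(seg$labels == segment)
  if (length(idx) == 0)
    stop(sprintf("segment '%s' is empty", segment), call. = FALSE)
  idx
}

#' Task completion time
#'
#' Time elapsed between the first and last sample of the selected segment,
#' `t_end - t_start`, in seconds.
#'
#' @param seg A [classify_segments()] result.
#' @param segment `"trial"` (the detected trial bounds) or a subtask label.
#' @return Seconds.
#' @export
completion_time <- function(seg, segment = "trial") {
  idx <- segment_indices(seg, segment)
  t <- seg$trial$t
  t[max(idx)] - t[min(idx)]
}

#' Exit point error
#'
#' Euclidean distance between the desired and actual needle exit points in
#' the plane of the tissue surface. Available only when an actual exit
#' point was measured (teleoperation trials); otherwise `NA`.
#'
#' @param geom A [tissue_geometry()].
#' @return Meters, or `NA_real_` when the actual exit point is absent.
#' @export
exit_point_error <- function(geom) {
  if (is.null(geom$actual_exit)) return(NA_real_)
  d <- surface_coords(rbind(geom$desired_exit, geom$actual_exit), geom)
  sqrt(sum((d[1, 1:2] - d[2, 1:2])^2))
}

#' Total normalized force
#'
#' Time integral of the force magnitude over the selected segment, divided
#' by `d_ie`, the Euclidean distance between the actual entrance and exit
#' points: `(1 / d_ie) * sum |f(n)| dt(n)`. Quantifies cumulative loading
#' of the tissue per unit distance traveled through it. `NA` when no actual
#' exit point is available (open setup).
#'
#' @inheritParams completion_time
#' @param geom A [tissue_geometry()].
#' @return N·s/m, or `NA_real_`.
#' @export
total_normalized_force <- function(seg, geom, segment = "trial") {
  die <- entrance_exit_distance(geom)
  if (is.null(die)) return(NA_real_)
  if (die <= 0) stop("entrance-exit distance must be positive", call. = FALSE)
  idx <- segment_indices(seg, segment)
  fmag <- row_norms(seg$trial$force[idx, , drop = FALSE])
  sum_dt(fmag, seg$trial$t[idx]) / die
}

#' Maximum force magnitude
#'
#' @inheritParams completion_time
#' @return Newtons.
#' @export
max_force <- function(seg, segment = "trial") {
  idx <- segment_indices(seg, segment)
  max(row_norms(seg$trial$force[idx, , drop = FALSE]))
}

#' Maximum torque about the tissue normal
#'
#' Maximum of `|tau_z|`, the torque about the vertical (tissue-normal)
#' axis, over the selected segment. Ideally zero: the optimal needle
#' driving movement is planar and does not rotate the needle about the
#' tissue normal.
#'
#' @inheritParams completion_time
#' @return N·m.
#' @export
max_torque_z <- function(seg, segment = "trial") {
  idx <- segment_indices(seg, segment)
  max(abs(seg$trial$torque[idx, 3]))
}

#' Path length
#'
#' Sum of consecutive Euclidean steps of the tooltip over the selected
#' segment. Always at least the straight-line endpoint distance.
#'
#' @inheritParams completion_time
#' @return Meters.
#' @export
path_length <- function(seg, segment = "trial") {
  idx <- segment_indices(seg, segment)
  p <- seg$trial$position[idx, , drop = FALSE]
  if (nrow(p) < 2) stop("need at least 2 samples", call. = FALSE)
  sum(row_norms(diff(p)))
}

#' Circle deviation
#'
#' Integrated squared radial deviation of the (plane-projected) path from
#' the fitted circle, against arc angle, normalized by the total arc path
#' `Theta_arc = radius * delta_theta_arc`:
#' `(1 / Theta_arc) * sum s^2(n) |dtheta(n)|`.
#'
#' @param fit A [fit_circle()] result.
#' @param radius Radius used in the `Theta_arc` normalizer. Defaults to the
#'   fitted radius; pass the nominal needle radius to normalize by the
#'   needle's arc instead.
#' @return m·rad (squared meters of deviation per meter of arc, integrated
#'   over angle).
#' @export
circle_deviation <- function(fit, radius = NULL) {
  stopifnot(inherits(fit, "circle_fit"))
  radius <- radius %||% fit$radius
  theta_arc <- radius * fit$delta_theta_arc
  if (theta_arc <= 0) stop("zero total arc path", call. = FALSE)
  sum(fit$s[-1]^2 * abs(diff(fit$theta))) / theta_arc
}

#' Plane deviation
#'
#' Integrated squared orthogonal distance of the path from its fitted
#' plane, against path length, normalized by the total path length:
#' `(1 / PL) * sum r^2(n) dx(n)` with `dx` the per-step path length.
#'
#' @param fit A [fit_plane()] result for `path`.
#' @param path The n x 3 path the plane was fitted to, m.
#' @return m^2.
#' @export
plane_deviation <- function(fit, path) {
  stopifnot(inherits(fit, "plane_fit"))
  path <- as.matrix(path)
  steps <- row_norms(diff(path))
  pl <- sum(steps)
  if (pl <= 0) stop("zero path length", call. = FALSE)
  sum(fit$distances[-1]^2 * steps) / pl
}

#' Normalized angular path
#'
#' Accumulated geodesic rotation angle between consecutive tooltip
#' orientations, divided by the path length; quantifies wrist rotation per
#' meter of tooltip travel during needle driving.
#'
#' @inheritParams completion_time
#' @return rad/m.
#' @export
angular_path <- function(seg, segment = "trial") {
  idx <- segment_indices(seg, segment)
  q <- seg$trial$quaternion[idx, , drop = FALSE]
  pl <- path_length(seg, segment)
  if (pl <= 0) stop("zero path length", call. = FALSE)
  sum(quat_step_angles(q)) / pl
}

#' Per-sample curvature and torsion
#'
#' Frenet curvature and torsion of the tooltip path from the derivative
#' chain: `kappa = |v x a| / |v|^3` and
#' `torsion = ((v x a) . j) / |v x a|^2`. Samples where the speed or the
#' `|v x a|` magnitude is below epsilon are flagged invalid rather than
#' producing unbounded values.
#'
#' @param trial A uniform trial with `velocity`, `acceleration` and `jerk`
#'   channels (see [derivative_chain()]).
#' @param min_speed Minimum speed for a valid sample, m/s. Default 1e-4.
#' @param min_cross Minimum `|v x a|` for a valid sample. Default 1e-12.
#' @return A data frame with columns `kappa` (1/m), `torsion` (1/m) and
#'   `valid`.
#' @export
curvature_torsion <- function(trial, min_speed = 1e-4, min_cross = 1e-12) {
  if (is.null(trial$velocity) || is.null(trial$acceleration) ||
      is.null(trial$jerk))
    stop("run derivative_chain() first", call. = FALSE)
  v <- trial$velocity; a <- trial$acceleration; j <- trial$jerk
  cr <- cbind(v[, 2] * a[, 3] - v[, 3] * a[, 2],
              v[, 3] * a[, 1] - v[, 1] * a[, 3],
              v[, 1] * a[, 2] - v[, 2] * a[, 1])
  sp <- row_norms(v)
  crn <- row_norms(cr)
  valid <- sp > min_speed & crn > min_cross
  kappa <- ifelse(valid, crn / sp^3, NA_real_)
  tors <- ifelse(valid, rowSums(cr * j) / crn^2, NA_real_)
  data.frame(kappa = kappa, torsion = tors, valid = valid)
}

#' Fit the speed-curvature-torsion power law
#'
#' Fits `v = alpha * kappa^beta * |torsion|^gamma` by ordinary least
#' squares on the log-transformed data: `log v` regressed on `log kappa`
#' and `log |torsion|`. In scribbling movements the exponents were proposed
#' to equal -1/3 and -1/6.
#'
#' @inheritParams curvature_torsion
#' @param indices Optional 1-based sample indices restricting the fit (e.g.
#'   an insertion segment).
#' @param min_torsion Samples with `|torsion|` below this (1/m) are
#'   excluded: the log of a near-zero torsion is unbounded. Default 1e-6.
#' @param min_samples Minimum valid samples required. Default 10.
#' @return An object of class `power_law_fit`: `alpha` (velocity gain),
#'   `beta`, `gamma` (exponents), `r_squared` of the log-space regression,
#'   `n_used`.
#' @export
fit_power_law <- function(trial, indices = NULL, min_speed = 1e-4,
                          min_torsion = 1e-6, min_samples = 10) {
  ct <- curvature_torsion(trial, min_speed = min_speed)
  sp <- row_norms(trial$velocity)
  keep <- ct$valid & sp > min_speed & abs(ct$torsion) > min_torsion
  if (!is.null(indices)) {
    sel <- rep(FALSE, length(keep)); sel[indices] <- TRUE
    keep <- keep & sel
  }
  n_used <- sum(keep)
  if (n_used < min_samples)
    stop(sprintf("only %d valid samples for the power-law fit (need >= %d)",
                 n_used, min_samples), call. = FALSE)
  y <- log(sp[keep]); x1 <- log(ct$kappa[keep]); x2 <- log(abs(ct$torsion[keep]))
  fit <- stats::lm(y ~ x1 + x2)
  r2 <- summary(fit)$r.squared
  cf <- coef(fit)
  structure(list(alpha = unname(exp(cf[1])), beta = unname(cf[2]),
                 gamma = unname(cf[3]), r_squared = r2, n_used = n_used),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> alpha = %.4g, beta = %.4f, gamma = %.4f, R^2 = %.4f (n = %d)\n",
              x$alpha, x$beta, x$gamma, x$r_squared, x$n_used))
  invisible(x)
}

#' Root-mean-squared jerk
#'
#' Duration-normalized root integral of the squared jerk magnitude,
#' `sqrt( (1/(t_end - t_start)) * sum |jerk(n)|^2 dt(n) )`, which has units
#' of jerk and is less correlated with completion time than unnormalized
#' integrals. Lower values mean smoother movement. Because it spans orders
#' of magnitude, downstream analysis uses `log10` of this value.
#'
#' @inheritParams completion_time
#' @return m/s^3.
#' @export
rms_jerk <- function(seg, segment = "trial") {
  idx <- segment_indices(seg, segment)
  if (is.null(seg$trial$jerk)) stop("run derivative_chain() first", call. = FALSE)
  t <- seg$trial$t[idx]
  dur <- t[length(t)] - t[1]
  if (dur <= 0) stop("zero segment duration", call. = FALSE)
  jm <- row_norms(seg$trial$jerk[idx, , drop = FALSE])
  sqrt(sum_dt(jm^2, t) / dur)
}

#' Compute the per-trial metric vector
#'
#' Runs the scalar metric suite on one segmented trial: completion time,
#' exit point error, total normalized force, max force, max torque about
#' the tissue normal, path length, circle deviation, plane deviation,
#' normalized angular path, power-law parameters, and log10 RMS jerk.
#' Consistency metrics (force / trajectory) are computed across blocks of
#' trials with [dtw_consistency()], not per trial. Metrics that are
#' unavailable for a trial (e.g. exit point error in the open setup) are
#' `NA`, and metrics whose fit fails (e.g. too few valid power-law samples)
#' are `NA` as well.
#'
#' @param seg A [classify_segments()] result on a preprocessed trial.
#' @param geom A [tissue_geometry()].
#' @param segment Subtask to score. Default `"insertion"`.
#' @param circle_radius Optional nominal needle radius for the circle
#'   deviation normalizer (default: fitted radius).
#' @return A one-row [tibble::tibble()] of metric values.
#' @export
compute_trial_metrics <- function(seg, geom, segment = "insertion",
                                  circle_radius = NULL) {
  idx <- segment_indices(seg, segment)
  p <- seg$trial$position[idx, , drop = FALSE]
  try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  plane <- tryCatch(fit_plane(p), error = function(e) NULL)
  circ <- if (!is.null(plane))
    tryCatch(fit_circle(p, plane), error = function(e) NULL) else NULL
  pl_fit <- tryCatch(fit_power_law(seg$trial, indices = idx),
                     error = function(e) NULL)
  tibble::tibble(
    completion_time = try_na(completion_time(seg, segment)),
    exit_point_error = exit_point_error(geom),
    total_normalized_force = try_na(total_normalized_force(seg, geom, segment)),
    max_force = try_na(max_force(seg, segment)),
    max_torque_z = try_na(max_torque_z(seg, segment)),
    force_consistency = NA_real_,
    path_length = try_na(path_length(seg, segment)),
    circle_deviation = if (is.null(circ)) NA_real_ else
      try_na(circle_deviation(circ, radius = circle_radius)),
    plane_deviation = if (is.null(plane)) NA_real_ else
      try_na(plane_deviation(plane, p)),
    angular_path = try_na(angular_path(seg, segment)),
    trajectory_consistency = NA_real_,
    powerlaw_alpha = if (is.null(pl_fit)) NA_real_ else pl_fit$alpha,
    powerlaw_beta = if (is.null(pl_fit)) NA_real_ else pl_fit$beta,
    powerlaw_gamma = if (is.null(pl_fit)) NA_real_ else pl_fit$gamma,
    log_jerk = try_na(log10(rms_jerk(seg, segment)))
  )
}
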