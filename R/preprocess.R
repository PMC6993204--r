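#' Resample a trial recording to a uniform rate
#'
#' Interpolates all channels of a raw variable-rate recording onto a uniform
#' grid: position, force and torque with shape-preserving piecewise-cubic
#' (monotone Hermite) interpolation, orientation with per-interval spherical
#' linear quaternion interpolation (after fixing the quaternion double cover
#' by sign continuity), and the categorical gripper channel with
#' nearest-previous-sample interpolation. The new grid spans only the
#' original time support; nothing is extrapolated.
#'
#' @param trial A [trial_recording()].
#' @param target_rate Target sampling rate, Hz. Default 100.
#' @return A [trial_recording()] on the uniform grid, with `meta$rate`
#'   updated.
#' @export
resample_to_uniform <- function(trial, target_rate = 100) {
  stopifnot(inherits(trial, "trial_recording"), target_rate > 0)
  t <- trial$t
  if (length(t) < 4) stop("need at least 4 samples to resample", call. = FALSE)
  if (any(diff(t) <= 0)) stop("duplicate or decreasing timestamps", call. = FALSE)
  tn <- seq(t[1], t[length(t)], by = 1 / target_rate)

  interp_cols <- function(m) {
    vapply(seq_len(ncol(m)), function(j)
      stats::splinefun(t, m[, j], method = "monoH.FC")(tn), numeric(length(tn)))
  }
  pos <- interp_cols(trial$position)
  frc <- interp_cols(trial$force)
  trq <- interp_cols(trial$torque)

  q <- quat_fix_signs(trial$quaternion)
  idx <- findInterval(tn, t, rightmost.closed = TRUE)
  idx <- clamp(idx, 1, length(t) - 1)
  u <- (tn - t[idx]) / (t[idx + 1] - t[idx])
  qi <- matrix(0, length(tn), 4)
  for (k in seq_along(tn))
    qi[k, ] <- quat_slerp(q[idx[k], ], q[idx[k] + 1, ], u[k])

  grip <- stats::approx(t, trial$gripper, xout = tn, method = "constant",
                        f = 0, rule = 2)$y

  meta <- trial$meta
  meta$rate <- target_rate
  trial_recording(tn, pos, qi, grip, frc, trq, meta)
}

# 2nd-order low-pass Butterworth design (delegated to signal::butter).
butter_coefs <- function(cutoff, rate, order = 2) {
  if (cutoff <= 0 || cutoff >= rate / 2)
    stop("`cutoff` must lie in (0, rate/2)", call. = FALSE)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

# Steady-state initial filter state for a unit-step input (so that constant
# signals pass through without transient). Companion-matrix construction.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  if (n == 1) return(numeric(0))
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(comp), b[-1] - a[-1] * b[1])
}

filtfilt_channel <- function(b, a, x) {
  n <- max(length(a), length(b))
  bb <- c(b, rep(0, n - length(b))) / a[1]
  aa <- c(a, rep(0, n - length(a))) / a[1]
  # pad until the slowest pole's transient decays below 1e-12, so the two
  # passes commute and filtering is time-reversal symmetric
  rmax <- max(Mod(polyroot(rev(aa))))
  npad <- max(3 * n, ceiling(log(1e-12) / log(min(rmax, 1 - 1e-9))))
  if (length(x) <= npad + 1)
    stop(sprintf("series too short to filter (need > %d samples)", npad + 1),
         call. = FALSE)
  zi <- lfilter_zi(bb, aa)
  # odd reflection padding suppresses edge transients
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  ext <- c(pre, x, post)
  y <- iir_filter_core(bb, aa, ext, zi * ext[1])
  y <- rev(iir_filter_core(bb, aa, rev(y), zi * y[length(y)]))
  y[(npad + 1):(npad + length(x))]
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Applies a 2nd-order Butterworth low-pass filter forward and backward
#' (zero phase lag) to a uniformly sampled series, per channel for matrix
#' input. Edge transients are suppressed with odd-reflection padding and
#' steady-state initial conditions. The double pass of a 10 Hz design has an
#' empirical -3 dB point of 8 Hz.
#'
#' @param series Numeric vector or matrix (one channel per column),
#'   uniformly sampled.
#' @param rate Sampling rate, Hz.
#' @param cutoff Single-pass cutoff frequency, Hz. Default 10.
#' @param order Filter order. Default 2.
#' @return Filtered series of the same shape.
#' @export
zero_phase_lowpass <- function(series, rate, cutoff = 10, order = 2) {
  co <- butter_coefs(cutoff, rate, order)
  if (is.null(dim(series)))
    return(filtfilt_channel(co$b, co$a, as.numeric(series)))
  out <- apply(series, 2, function(x) filtfilt_channel(co$b, co$a, x))
  dimnames(out) <- dimnames(series)
  out
}

# Central-difference differentiation on a uniform grid; one-sided at the
# edges. Vector or matrix (per column).
central_diff <- function(x, dt) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  d <- (x[c(2:n, n), , drop = FALSE] - x[c(1, 1:(n - 1)), , drop = FALSE]) /
    (dt * c(1, rep(2, n - 2), 1))
  d
}

#' Differentiate a uniform trial into velocity, acceleration and jerk
#'
#' Computes velocity, acceleration and jerk from the (already filtered)
#' position channel by central-difference differentiation, re-filtering the
#' result after each differentiation with the same zero-phase low-pass
#' filter used for position. Edge samples carry one-sided-difference and
#' filter-transient error; interior samples are accurate.
#'
#' @param trial A uniform-rate [trial_recording()] whose position channel
#'   has been filtered.
#' @param cutoff,order Filter parameters passed to [zero_phase_lowpass()].
#' @return The trial with `velocity` (m/s), `acceleration` (m/s^2) and
#'   `jerk` (m/s^3) matrices added.
#' @export
derivative_chain <- function(trial, cutoff = 10, order = 2) {
  stopifnot(inherits(trial, "trial_recording"))
  if (!is_uniform(trial, tol = 1e-6))
    stop("`trial` must be uniformly sampled", call. = FALSE)
  rate <- sample_rate(trial)
  dt <- 1 / rate
  v <- zero_phase_lowpass(central_diff(trial$position, dt), rate, cutoff, order)
  a <- zero_phase_lowpass(central_diff(v, dt), rate, cutoff, order)
  j <- zero_phase_lowpass(central_diff(a, dt), rate, cutoff, order)
  trial$velocity <- v
  trial$acceleration <- a
  trial$jerk <- j
  trial
}

#' Full preprocessing of a raw trial
#'
#' Convenience wrapper running the preprocessing stage end to end: resample
#' to the target rate, low-pass filter the tooltip position, and compute the
#' filtered derivative chain. Force, torque and gripper channels are
#' resampled but not filtered, preserving the force-threshold structure used
#' by the segmentation stage.
#'
#' @param trial A raw [trial_recording()].
#' @param target_rate Target uniform rate, Hz. Default 100.
#' @param cutoff,order Filter parameters. Defaults 10 Hz, order 2.
#' @return A uniform trial with derived channels (a "uniform trial").
#' @export
preprocess_trial <- function(trial, target_rate = 100, cutoff = 10, order = 2) {
  u <- resample_to_uniform(trial, target_rate)
  u$position <- zero_phase_lowpass(u$position, target_rate, cutoff, order)
  derivative_chain(u, cutoff = cutoff, order = order)
}
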