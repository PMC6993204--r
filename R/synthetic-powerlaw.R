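#' Base path for power-law trajectories
#'
#' A smooth 3-D "scribbling" curve with nonvanishing curvature and torsion:
#' a circular sweep with a radial perturbation (modulating curvature) and a
#' climbing, undulating vertical component (modulating torsion), the two at
#' incommensurate frequencies so curvature and torsion vary independently.
#'
#' @param radius Mean horizontal radius, m. Default 0.06.
#' @param radial_amp,radial_freq Radial perturbation amplitude (m) and
#'   frequency (per rad of sweep).
#' @param climb Vertical climb rate, m per rad of sweep.
#' @param vert_amp,vert_freq Vertical undulation amplitude (m) and
#'   frequency (per rad of sweep).
#' @param u_range Parameter range of the sweep, rad.
#' @return A list with the position function `f(u)` (n x 3 matrix) and
#'   `u_range`, usable as `base_path` in [generate_powerlaw_trajectory()].
#' @export
scribble_path <- function(radius = 0.06, radial_amp = 0.002,
                          radial_freq = 2.7, climb = 0.018,
                          vert_amp = 0.0008, vert_freq = 1.3,
                          u_range = c(0, 4 * pi)) {
  f <- function(u) {
    r <- radius + radial_amp * sin(radial_freq * u)
    cbind(r * cos(u), r * sin(u),
          climb * u + vert_amp * sin(vert_freq * u + 0.5))
  }
  list(f = f, u_range = u_range)
}

# First three derivatives of a curve function by high-order central
# differences (5-point stencils) at parameter values u.
curve_derivatives <- function(f, u, h = 1e-3) {
  fm2 <- f(u - 2 * h); fm1 <- f(u - h); fp1 <- f(u + h); fp2 <- f(u + 2 * h)
  f0 <- f(u)
  d1 <- (fm2 - 8 * fm1 + 8 * fp1 - fp2) / (12 * h)
  d2 <- (-fm2 + 16 * fm1 - 30 * f0 + 16 * fp1 - fp2) / (12 * h^2)
  d3 <- (fp2 - 2 * fp1 + 2 * fm1 - fm2) / (2 * h^3)
  list(d1 = d1, d2 = d2, d3 = d3)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Generate a trajectory exactly obeying the speed-curvature-torsion law
#'
#' Time-reparameterizes a geometric base path so that the sampled speed
#' satisfies `v = alpha * kappa^beta * |torsion|^gamma` at every sample,
#' given the path's curvature and torsion. With `beta = gamma = 0` the
#' result moves at constant speed `alpha`. Fitting the power law to the
#' (noiseless) output recovers the generating parameters.
#'
#' @param alpha Velocity gain factor, m/s (for `beta = gamma = 0` it is the
#'   constant speed).
#' @param beta,gamma Curvature and torsion exponents (dimensionless); the
#'   theoretical scribbling values are -1/3 and -1/6.
#' @param base_path A path spec as returned by [scribble_path()] (function
#'   `f(u)` plus `u_range`); curvature and torsion must be nonvanishing
#'   along it.
#' @param sample_rate Output sampling rate, Hz. Default 100.
#' @param min_torsion Minimum admissible `|torsion|` (1/m) along the base
#'   path; the generator refuses paths that are flat (zero torsion) or
#'   straight (zero curvature) over a finite stretch. Default 1e-4.
#' @param n_grid Quadrature grid size for the time reparameterization.
#' @return A [trial_recording()] sampled uniformly at `sample_rate` (zero
#'   forces, constant orientation).
#' @export
generate_powerlaw_trajectory <- function(alpha, beta, gamma,
                                         base_path = scribble_path(),
                                         sample_rate = 100,
                                         min_torsion = 1e-4,
                                         n_grid = 8000) {
  stopifnot(alpha > 0, sample_rate > 0)
  ug <- seq(base_path$u_range[1], base_path$u_range[2], length.out = n_grid)
  dv <- curve_derivatives(base_path$f, ug)
  cr <- cross3(dv$d1, dv$d2)
  sp_u <- row_norms(dv$d1)                     # |dr/du|
  crn <- row_norms(cr)
  kappa <- crn / sp_u^3
  torsion <- rowSums(cr * dv$d3) / crn^2
  if (any(!is.finite(kappa)) || any(kappa < 1e-9))
    stop("base path has vanishing curvature", call. = FALSE)
  if (any(!is.finite(torsion)) || any(abs(torsion) < min_torsion))
    stop("base path has vanishing torsion", call. = FALSE)

  v <- alpha * kappa^beta * abs(torsion)^gamma
  dt_du <- sp_u / v
  tg <- cumsum(c(0, (dt_du[-1] + dt_du[-n_grid]) / 2 * diff(ug)))
  u_of_t <- stats::splinefun(tg, ug, method = "monoH.FC")
  ts <- seq(0, tg[n_grid], by = 1 / sample_rate)
  pos <- base_path$f(u_of_t(ts))

  n <- length(ts)
  z3 <- matrix(0, n, 3)
  q <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  trial_recording(ts, pos, q, rep(0.8, n), z3, z3,
                  meta = list(setup = "teleop", rate = sample_rate,
                              synthetic = TRUE, powerlaw = c(alpha = alpha,
                                                             beta = beta,
                                                             gamma = gamma)))
}
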