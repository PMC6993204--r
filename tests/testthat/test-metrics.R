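# Helper: a segmented trial whose bounds span all samples (constant
# suprathreshold force inside the contour).
make_full_seg <- function(pos, rate = 100, quaternion = NULL, force = NULL,
                          torque = NULL, geom = make_geometry()) {
  n <- nrow(pos)
  tr <- make_uniform_trial(pos, rate, quaternion,
                           force %||% cbind(rep(1, n), 0, 0), torque = torque)
  classify_segments(tr, geom)
}

test_that("completion time is the elapsed time over the segment bounds", {
  n <- 401
  seg <- make_full_seg(cbind(seq(-0.02, 0.02, length.out = n), 0, 0))
  expect_equal(completion_time(seg), 4.0)
  # offset time origin
  seg$trial$t <- seg$trial$t + 1.2
  expect_equal(completion_time(seg), 4.0)
  expect_equal(seg$trial$t[seg$bounds[1] + 1], 1.2)
})

test_that("exit point error is the in-plane distance to the desired exit", {
  g <- tissue_geometry(entrance_point = c(-0.02, 0, 0),
                       desired_exit = c(0, 0, 0),
                       actual_exit = c(0.003, 0.004, 0))
  expect_equal(exit_point_error(g), 0.005)   # 3-4-5 triangle
  g2 <- tissue_geometry(entrance_point = c(-0.02, 0, 0),
                        desired_exit = c(0.01, 0.01, 0),
                        actual_exit = c(0.01, 0.01, 0))
  expect_equal(exit_point_error(g2), 0)
  g3 <- tissue_geometry(entrance_point = c(-0.02, 0, 0),
                        desired_exit = c(0.01, 0.01, 0))
  expect_true(is.na(exit_point_error(g3)))   # open setup: no actual exit
  # random pairs against a direct distance computation
  set.seed(6)
  for (k in 1:10) {
    a <- runif(2, -0.02, 0.02); b <- runif(2, -0.02, 0.02)
    gk <- tissue_geometry(entrance_point = c(-0.03, 0, 0),
                          desired_exit = c(a, 0), actual_exit = c(b, 0))
    expect_equal(exit_point_error(gk), sqrt(sum((a - b)^2)))
  }
})

test_that("total normalized force integrates |f| dt over d_ie", {
  n <- 201   # exactly 2 s at 100 Hz
  geom <- make_geometry(actual_exit = c(0, 0.02, 0))
  geom$entrance_point <- c(-0.012, 0.004, 0)          # 0.02 from actual exit
  die <- sqrt(sum((geom$entrance_point - geom$actual_exit)^2))
  expect_equal(die, 0.02)
  seg <- make_full_seg(cbind(seq(-0.01, 0.01, length.out = n), 0, 0),
                       geom = geom)
  expect_equal(total_normalized_force(seg, geom), 2 / 0.02)   # 100 N.s/m

  # ramp force against an explicit per-sample oracle
  f <- cbind(seq(0.1, 2, length.out = n), 0, 0)
  seg2 <- make_full_seg(cbind(seq(-0.01, 0.01, length.out = n), 0, 0),
                        force = f, geom = geom)
  oracle <- sum(f[-1, 1] * diff(seg2$trial$t)) / die
  expect_equal(total_normalized_force(seg2, geom), oracle, tolerance = 1e-9)

  # unavailable without an actual exit point
  g0 <- make_geometry(actual_exit = NULL)
  expect_true(is.na(total_normalized_force(seg, g0)))
})

test_that("force and torque maxima scan the bounded samples", {
  n <- 301
  f <- cbind(rep(0.5, n), 0, 0)
  f[150, ] <- c(3, 0, 0)
  tq <- matrix(0, n, 3)
  tq[200, 3] <- -0.04                        # sign-invariant
  seg <- make_full_seg(cbind(seq(-0.02, 0.02, length.out = n), 0, 0),
                       force = f, torque = tq)
  expect_equal(max_force(seg), 3)
  expect_equal(max_torque_z(seg), 0.04)
  set.seed(7)
  fr <- cbind(abs(rnorm(n)) + 0.1, rnorm(n), rnorm(n))
  segr <- make_full_seg(cbind(seq(-0.02, 0.02, length.out = n), 0, 0),
                        force = fr)
  expect_equal(max_force(segr), max(sqrt(rowSums(fr^2))))
})

test_that("path length sums Euclidean steps and bounds the chord", {
  n <- 101
  seg <- make_full_seg(cbind(seq(0, 0.1, length.out = n), 0, 0),
                       geom = make_geometry(half_side = 0.2))
  expect_equal(path_length(seg), 0.1)
  # dense semicircle
  th <- seq(0, pi, length.out = 2000)
  r <- 0.02
  segc <- make_full_seg(cbind(r * cos(th), r * sin(th), 0))
  expect_equal(path_length(segc), pi * r, tolerance = 1e-5)
  # never below the straight-line endpoint distance
  set.seed(8)
  pos <- cbind(cumsum(rnorm(50, 0, 1e-3)), cumsum(rnorm(50, 0, 1e-3)), 0)
  segw <- make_full_seg(pos, geom = make_geometry(half_side = 1))
  expect_gte(path_length(segw), sqrt(sum((pos[50, ] - pos[1, ])^2)))
})

test_that("plane and circle fits recover exact geometry and reject degeneracy", {
  th <- seq(0.2, 2.4, length.out = 300)
  r <- 0.0187
  circ <- cbind(r * cos(th), r * sin(th), rep(0.005, 300))
  pf <- fit_plane(circ)
  expect_lt(max(pf$distances), 1e-9)
  cf <- fit_circle(circ, pf)
  expect_equal(cf$radius, r, tolerance = 1e-9)
  expect_lt(max(abs(cf$s)), 1e-9)
  expect_equal(cf$delta_theta_arc, 2.2, tolerance = 1e-9)
  # theta is monotone along a simple arc
  expect_true(all(diff(cf$theta) > 0) || all(diff(cf$theta) < 0))

  expect_error(fit_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")

  # noisy circle: geometric fit agrees with an independent full nonlinear
  # least-squares (Levenberg-Marquardt) oracle over (cx, cy, r)
  set.seed(9)
  noisy <- circ + cbind(rnorm(300, 0, 2e-4), rnorm(300, 0, 2e-4), 0)
  cfn <- fit_circle(noisy)
  xy <- needlekin:::plane_project(cfn$plane, noisy)$xy
  oracle <- minpack.lm::nls.lm(
    par = c(0, 0, r),
    fn = function(p) sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2) - p[3],
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15))
  expect_equal(unname(cfn$center), oracle$par[1:2], tolerance = 1e-6)
  expect_equal(cfn$radius, oracle$par[3], tolerance = 1e-6)
})

test_that("circle deviation matches its closed forms and scales linearly", {
  th <- seq(0.2, 2.4, length.out = 300)
  r <- 0.02
  circ <- cbind(r * cos(th), r * sin(th), 0)
  cf <- fit_circle(circ)
  expect_lt(circle_deviation(cf), 1e-12)

  # constant radial offset s0: deviation = s0^2 / r
  s0 <- 0.0015
  off <- cbind((r + s0) * cos(th), (r + s0) * sin(th), 0)
  cf_off <- needlekin:::circle_eval(cf, off)
  expect_equal(circle_deviation(cf_off), s0^2 / r, tolerance = 1e-9)

  # spatial scaling by c scales the metric by c
  set.seed(10)
  wob <- circ + cbind(rnorm(300, 0, 1e-4), rnorm(300, 0, 1e-4), 0)
  for (cc in c(0.5, 2, 3.7)) {
    d1 <- circle_deviation(fit_circle(wob))
    d2 <- circle_deviation(fit_circle(cc * wob))
    expect_equal(d2, cc * d1, tolerance = 1e-6)
  }
})

test_that("plane deviation matches a quadrature oracle and scales quadratically", {
  x <- seq(0, 0.1, length.out = 1001)
  A <- 0.002
  ripple <- cbind(x, 0, A * sin(2 * pi * 5 * x / 0.1))  # 5 full periods
  pf <- fit_plane(ripple)
  pd <- plane_deviation(pf, ripple)
  expect_equal(pd, A^2 / 2, tolerance = 1e-2)           # mean of sin^2

  # exactly planar (non-collinear) path: zero
  flat <- cbind(x, 0.01 * sin(40 * x), 0.3 * x - 0.2 * 0.01 * sin(40 * x) + 1)
  expect_lt(plane_deviation(fit_plane(flat), flat), 1e-18)

  # exact per-sample oracle
  steps <- sqrt(rowSums(diff(ripple)^2))
  oracle <- sum(pf$distances[-1]^2 * steps) / sum(steps)
  expect_equal(pd, oracle, tolerance = 1e-12)

  for (cc in c(0.5, 2)) {
    pfc <- fit_plane(cc * ripple)
    expect_equal(plane_deviation(pfc, cc * ripple), cc^2 * pd,
                 tolerance = 1e-9)
  }
})

test_that("angular path accumulates geodesic rotation per meter traveled", {
  n <- 101
  pos <- cbind(seq(0, 0.1, length.out = n), 0, 0)
  ang <- seq(0, pi / 2, length.out = n)
  q <- needlekin:::quat_from_axis_angle(c(0, 0, 1), ang)
  seg <- make_full_seg(pos, quaternion = q,
                       geom = make_geometry(half_side = 0.2))
  expect_equal(angular_path(seg), (pi / 2) / 0.1, tolerance = 1e-9)

  # constant orientation: zero
  seg0 <- make_full_seg(pos, geom = make_geometry(half_side = 0.2))
  expect_equal(angular_path(seg0), 0)

  # random orientation walk against an independent axis-angle accumulation
  set.seed(11)
  dang <- abs(rnorm(n - 1, 0, 0.03))
  q2 <- needlekin:::quat_from_axis_angle(c(1, 1, 0), cumsum(c(0, dang)))
  seg2 <- make_full_seg(pos, quaternion = q2,
                        geom = make_geometry(half_side = 0.2))
  expect_equal(angular_path(seg2), sum(dang) / 0.1, tolerance = 1e-9)
})

test_that("curvature and torsion recover textbook closed forms", {
  # planar circle at constant speed: kappa = 1/R, torsion = 0
  R <- 0.05; w <- 2 * pi * 0.4
  t <- seq(0, 6, by = 0.01)
  tr <- make_uniform_trial(cbind(R * cos(w * t), R * sin(w * t), 0))
  u <- derivative_chain(tr)
  ct <- curvature_torsion(u)
  i <- 80:520
  expect_equal(ct$kappa[i], rep(1 / R, length(i)), tolerance = 1e-3)
  expect_lt(max(abs(ct$torsion[i])), 1e-2)

  # circular helix: kappa = R/(R^2+c^2), torsion = c/(R^2+c^2)
  cc <- 0.02
  trh <- make_uniform_trial(cbind(R * cos(w * t), R * sin(w * t), cc * w * t))
  uh <- derivative_chain(trh)
  cth <- curvature_torsion(uh)
  expect_equal(cth$kappa[i], rep(R / (R^2 + cc^2), length(i)),
               tolerance = 1e-3)
  expect_equal(cth$torsion[i], rep(cc / (R^2 + cc^2), length(i)),
               tolerance = 1e-3)

  # straight line: flagged invalid, not infinite
  trl <- make_uniform_trial(cbind(0.01 * t, 0, 0))
  ul <- derivative_chain(trl)
  ctl <- curvature_torsion(ul)
  expect_true(all(!ctl$valid[i] | ctl$kappa[i] < 1e-6))
})

test_that("power-law fit equals an independent least-squares oracle", {
  tr <- generate_powerlaw_trajectory(0.05, -1/3, -1/6)
  u <- derivative_chain(tr)
  fit <- fit_power_law(u)
  # independent normal-equations oracle on the same flagged samples
  ct <- curvature_torsion(u)
  sp <- sqrt(rowSums(u$velocity^2))
  keep <- ct$valid & sp > 1e-4 & abs(ct$torsion) > 1e-6
  X <- cbind(1, log(ct$kappa[keep]), log(abs(ct$torsion[keep])))
  beta_hat <- solve(crossprod(X), crossprod(X, log(sp[keep])))
  expect_equal(fit$alpha, exp(beta_hat[1]), tolerance = 1e-9)
  expect_equal(fit$beta, beta_hat[2], tolerance = 1e-9)
  expect_equal(fit$gamma, beta_hat[3], tolerance = 1e-9)
  expect_equal(fit$n_used, sum(keep))

  # constant-speed trajectory: both exponents near zero
  tr0 <- generate_powerlaw_trajectory(0.05, 0, 0)
  f0 <- fit_power_law(derivative_chain(tr0))
  expect_lt(abs(f0$beta), 5e-3)
  expect_lt(abs(f0$gamma), 5e-3)
  expect_equal(f0$alpha, 0.05, tolerance = 1e-2)

  # doubling alpha doubles the fitted gain, exponents unchanged
  tr2 <- generate_powerlaw_trajectory(0.10, 0, 0)
  f2 <- fit_power_law(derivative_chain(tr2))
  expect_equal(f2$alpha / f0$alpha, 2, tolerance = 1e-2)
})

test_that("RMS jerk matches closed forms and scales as c^-3 under time dilation", {
  n <- 301
  pos <- cbind(seq(0, 0.1, length.out = n), 0, 0)
  seg <- make_full_seg(pos, geom = make_geometry(half_side = 0.2))
  j0 <- 0.8
  seg$trial$jerk <- cbind(rep(j0, n), 0, 0)
  expect_equal(rms_jerk(seg), j0, tolerance = 1e-12)

  # 1-D minimum-jerk reach: discrete rule against analytic quadrature of the
  # quintic's third derivative
  D <- 0.1; Tm <- 1.5
  t <- seq(0, Tm, by = 0.01)
  s <- t / Tm
  jerk_a <- D / Tm^3 * (60 - 360 * s + 360 * s^2)
  segm <- make_full_seg(cbind(D * (10 * s^3 - 15 * s^4 + 6 * s^5), 0, 0),
                        geom = make_geometry(half_side = 0.2))
  segm$trial$jerk <- cbind(jerk_a, 0, 0)
  analytic <- sqrt(D^2 / Tm^6 * 720)   # closed form of the quintic integral
  expect_equal(rms_jerk(segm), analytic, tolerance = 1e-2)

  # time dilation by c: jerk metric scales by c^-3 (analytic resampling)
  A <- 0.02; w <- 2 * pi
  base <- function(cdil) {
    tt <- seq(0, 3 * cdil, by = 0.01)
    trd <- make_uniform_trial(cbind(A * sin(w * tt / cdil), 0, 0))
    ud <- derivative_chain(trd)
    nn <- length(tt)
    jm <- sqrt(rowSums(ud$jerk^2))
    i <- 100:(nn - 100)
    sqrt(mean(jm[i]^2))             # interior RMS, edges carry transients
  }
  expect_equal(base(2) / base(1), 2^-3, tolerance = 1e-2)
})

test_that("metrics are invariant under rigid motion of the whole scene", {
  cfg <- trial_config(seed = 5)
  gt <- generate_trial(cfg)
  u <- preprocess_trial(gt$trial)
  seg <- classify_segments(u, gt$geom)
  m1 <- compute_trial_metrics(seg, gt$geom)

  R <- random_rotation(12)
  shift <- c(0.2, -0.1, 0.35)
  u2 <- rigid_transform_trial(u, R, shift)
  geom2 <- needlekin:::transform_geometry(gt$geom, R, shift)
  seg2 <- classify_segments(u2, geom2)
  m2 <- compute_trial_metrics(seg2, geom2)

  for (mm in c("completion_time", "exit_point_error",
               "total_normalized_force", "max_force", "path_length",
               "circle_deviation", "plane_deviation", "angular_path",
               "log_jerk")) {
    expect_equal(m2[[mm]], m1[[mm]], tolerance = 1e-9, label = mm)
  }
})

test_that("the metric vector flags unavailable metrics as NA, not zero", {
  cfg <- trial_config(seed = 6)
  gt <- generate_trial(cfg)
  u <- preprocess_trial(gt$trial)
  geom_open <- gt$geom
  geom_open$actual_exit <- NULL            # open setup
  seg <- classify_segments(u, geom_open)
  m <- compute_trial_metrics(seg, geom_open)
  expect_true(is.na(m$exit_point_error))
  expect_true(is.na(m$total_normalized_force))
  expect_false(is.na(m$completion_time))
  expect_gt(m$completion_time, 0)
  expect_true(all(unlist(m[c("path_length", "circle_deviation",
                             "plane_deviation", "angular_path")]) >= 0))
})
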