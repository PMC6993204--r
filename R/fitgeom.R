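#' Fit a plane to a 3-D path
#'
#' Least-squares plane through a tooltip path, fitted as a linear regression
#' of the out-of-plane coordinate on the two in-plane coordinates. The
#' regression frame is chosen automatically by principal component analysis
#' of the path (the smallest-variance direction becomes the dependent axis),
#' which keeps the regression well conditioned for movement planes of any
#' orientation — including the near-vertical planes typical of needle
#' insertion, where a fixed world-z regression would be rank deficient.
#'
#' @param path n x 3 matrix of positions, m.
#' @return An object of class `plane_fit` with the regression coefficients
#'   `c(a, b, c)` (plane `z' = a x' + b y' + c` in the chosen frame), the
#'   frame `rotation` and `centroid`, per-sample orthogonal `distances`
#'   (>= 0, m), and `r_squared`.
#' @export
fit_plane <- function(path) {
  path <- as.matrix(path)
  stopifnot(ncol(path) == 3)
  if (nrow(path) < 3) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(path)
  centered <- sweep(path, 2, ctr)
  sv <- svd(centered)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate path: points are collinear", call. = FALSE)
  rot <- sv$v                       # columns: PC1, PC2, PC3 (world -> frame)
  f <- centered %*% rot
  fit <- stats::lm.fit(cbind(1, f[, 1:2]), f[, 3])
  cf <- c(a = unname(fit$coefficients[2]), b = unname(fit$coefficients[3]),
          c = unname(fit$coefficients[1]))
  s <- sqrt(1 + cf[1]^2 + cf[2]^2)
  dist <- abs(fit$residuals) / s
  sst <- sum((f[, 3] - mean(f[, 3]))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 1
  structure(list(coefficients = cf, rotation = rot, centroid = ctr,
                 distances = unname(dist), r_squared = unname(r2)),
            class = "plane_fit")
}

# Project world points onto the fitted plane; returns in-plane 2-D
# coordinates and signed orthogonal distances.
plane_project <- function(fit, path) {
  f <- sweep(as.matrix(path), 2, fit$centroid) %*% fit$rotation
  cf <- fit$coefficients
  s <- sqrt(1 + cf[1]^2 + cf[2]^2)
  nrm <- c(-cf[1], -cf[2], 1) / s
  d0 <- cf[3] / s                         # plane offset along the normal
  h <- f %*% nrm - d0                     # signed distance to plane
  proj <- f - outer(as.numeric(h), nrm)
  u1 <- c(1, 0, cf[1]); u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(nrm[2] * u1[3] - nrm[3] * u1[2],
          nrm[3] * u1[1] - nrm[1] * u1[3],
          nrm[1] * u1[2] - nrm[2] * u1[1])
  p0 <- c(0, 0, cf[3])
  rel <- sweep(proj, 2, p0)
  list(xy = cbind(rel %*% u1, rel %*% u2), dist = as.numeric(h))
}

#' Fit a circle to a (projected) 3-D path
#'
#' Projects the path onto its fitted plane and fits a circle to the
#' projection: an algebraic least-squares (Kasa) fit followed by geometric
#' refinement of the center (minimizing the sum of squared radial
#' residuals, with the radius profiled out as the mean center distance).
#' For an ideal insertion the fitted circle has the radius of the surgical
#' needle.
#'
#' @param path n x 3 matrix of positions, m.
#' @param plane A [fit_plane()] result; computed from `path` when `NULL`.
#' @return An object of class `circle_fit` with the `plane`, 2-D `center`,
#'   `radius` (m), per-sample in-plane radial deviations `s` (signed, m),
#'   unwrapped arc angles `theta` (rad), swept angle `delta_theta_arc`
#'   (rad), and the fitting projection.
#' @export
fit_circle <- function(path, plane = NULL) {
  path <- as.matrix(path)
  if (is.null(plane)) plane <- fit_plane(path)
  pr <- plane_project(plane, path)
  xy <- pr$xy
  if (nrow(xy) < 3) stop("need at least 3 points", call. = FALSE)
  # Kasa: x^2 + y^2 = 2 cx x + 2 cy y + (r^2 - cx^2 - cy^2)
  A <- cbind(2 * xy[, 1], 2 * xy[, 2], 1)
  rhs <- xy[, 1]^2 + xy[, 2]^2
  sol <- tryCatch(qr.solve(A, rhs),
                  error = function(e) stop("degenerate path: cannot fit a ",
                                           "circle", call. = FALSE))
  center <- sol[1:2]
  # geometric refinement: minimize sum (d_i - mean(d))^2 over the center,
  # with the radius profiled out as the mean center distance
  obj <- function(cc) {
    d <- sqrt((xy[, 1] - cc[1])^2 + (xy[, 2] - cc[2])^2)
    sum((d - mean(d))^2)
  }
  grad <- function(cc) {
    dx <- xy[, 1] - cc[1]; dy <- xy[, 2] - cc[2]
    d <- sqrt(dx^2 + dy^2)
    w <- (d - mean(d)) / pmax(d, 1e-300)
    -2 * c(sum(w * dx), sum(w * dy))
  }
  opt <- stats::optim(center, obj, grad, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 500))
  center <- opt$par
  # Gauss-Newton polish to machine precision (makes the minimizer
  # independent of the coordinate frame used for the projection)
  for (it in 1:30) {
    dx <- xy[, 1] - center[1]; dy <- xy[, 2] - center[2]
    d <- pmax(sqrt(dx^2 + dy^2), 1e-300)
    res <- d - mean(d)
    J <- cbind(-dx / d + mean(dx / d), -dy / d + mean(dy / d))
    step <- tryCatch(solve(crossprod(J), -crossprod(J, res)),
                     error = function(e) NULL)
    if (is.null(step)) break
    center <- center + as.numeric(step)
    if (max(abs(step)) < 1e-15 * max(1e-12, max(abs(center)))) break
  }
  d <- sqrt((xy[, 1] - center[1])^2 + (xy[, 2] - center[2])^2)
  radius <- mean(d)
  if (!is.finite(radius) || radius <= 0)
    stop("degenerate path: non-positive fitted radius", call. = FALSE)
  theta <- unwrap_angles(atan2(xy[, 2] - center[2], xy[, 1] - center[1]))
  structure(list(plane = plane, center = center, radius = radius,
                 s = d - radius, theta = theta,
                 delta_theta_arc = abs(theta[length(theta)] - theta[1]),
                 xy = xy),
            class = "circle_fit")
}

unwrap_angles <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(theta[1], d))
}

# Re-evaluate an existing circle fit against a new path (same plane, same
# circle): per-sample radial deviation and arc angle.
circle_eval <- function(fit, path) {
  pr <- plane_project(fit$plane, as.matrix(path))
  xy <- pr$xy
  d <- sqrt((xy[, 1] - fit$center[1])^2 + (xy[, 2] - fit$center[2])^2)
  theta <- unwrap_angles(atan2(xy[, 2] - fit$center[2],
                               xy[, 1] - fit$center[1]))
  out <- fit
  out$s <- d - fit$radius
  out$theta <- theta
  out$delta_theta_arc <- abs(theta[length(theta)] - theta[1])
  out$xy <- xy
  out
}
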