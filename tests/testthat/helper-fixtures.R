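# Fixture builders and independent oracles used across the suite.

identity_quat <- function(n) matrix(rep(c(1, 0, 0, 0), each = n), n, 4)

# Minimal uniform trial from a position matrix (zero force/torque).
make_uniform_trial <- function(pos, rate = 100, quaternion = NULL,
                               force = NULL, gripper = NULL, torque = NULL) {
  n <- nrow(pos)
  t <- seq(0, by = 1 / rate, length.out = n)
  trial_recording(t, pos,
                  quaternion %||% identity_quat(n),
                  gripper %||% rep(0.1, n),
                  force %||% matrix(0, n, 3),
                  torque %||% matrix(0, n, 3),
                  meta = list(rate = rate))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Geometry with a wide square contour around the origin.
make_geometry <- function(half_side = 0.05, actual_exit = c(0.02, 0, 0)) {
  tissue_geometry(contour = rbind(c(-half_side, -half_side),
                                  c(half_side, -half_side),
                                  c(half_side, half_side),
                                  c(-half_side, half_side)),
                  entrance_point = c(-0.02, 0, 0),
                  desired_exit = c(0.021, 0.001, 0),
                  actual_exit = actual_exit)
}

# Uniform trial whose force exceeds the threshold exactly on the 0-based
# sample range [i0, i1], tooltip always inside the contour.
make_bounds_trial <- function(i0 = 120, i1 = 840, n = 1000, f_on = 0.5) {
  pos <- cbind(seq(-0.02, 0.02, length.out = n), 0, 0)
  f <- matrix(0, n, 3)
  f[(i0 + 1):(i1 + 1), 1] <- f_on
  make_uniform_trial(pos, force = f)
}

# --- independent statistical oracles ---------------------------------------

# Exhaustive sign-flip enumeration of the two-sided signed-rank p-value.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- signs %*% r
  min(1, 2 * min(mean(Vs >= V), mean(Vs <= V)))
}

# Kruskal-Wallis H by direct evaluation of the rank formula (tie corrected).
kw_H_oracle <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (N + 1)
  tie <- table(r)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# Full permutation distribution of H: p = P(H_perm >= H_obs).
enum_kw_p <- function(values, groups) {
  groups <- as.integer(factor(groups))
  H_obs <- kw_H_oracle(values, groups)
  n <- length(values)
  sizes <- as.integer(table(groups))
  perms <- list()
  rec <- function(remaining, g, lab) {
    if (g == length(sizes)) {
      lab[remaining] <- g
      perms[[length(perms) + 1L]] <<- lab
      return(invisible())
    }
    for (cc in utils::combn(remaining, sizes[g], simplify = FALSE)) {
      l2 <- lab; l2[cc] <- g
      rec(setdiff(remaining, cc), g + 1L, l2)
    }
  }
  rec(seq_len(n), 1L, integer(n))
  Hs <- vapply(perms, function(g) kw_H_oracle(values, g), numeric(1))
  mean(Hs >= H_obs - 1e-12)
}

# Trapezoid quadrature oracle for sum-of-f*dt style integrals.
trapz <- function(t, y) sum((y[-1] + y[-length(y)]) / 2 * diff(t))

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
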