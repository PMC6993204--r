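#' Synthetic trial configuration
#'
#' Parameters of the synthetic needle-driving trial generator. The
#' generator emulates a needle-driver tooltip following the arc of a curved
#' surgical needle through a planar artificial tissue, with the
#' phase-structured tissue-interaction force pattern of a correctly
#' performed trial and the subtask structure of the task (positioning,
#' insertion, optional correction, repositioning, extraction).
#'
#' @param needle_radius Radius of the needle's arc, m. Default 0.0187
#'   (a large half-circle surgical needle).
#' @param arc_span Angular extent of the insertion arc, rad. Default
#'   `5 * pi / 6`.
#' @param sample_rate Native sampling rate, Hz: 120 (open setup) or 500
#'   (teleoperation). Default 120.
#' @param subtask_schedule Data frame with columns `label` and `duration`
#'   (s) giving the ordered subtask phases. Labels are `outside`,
#'   `insertion`, `correction`, `reposition`, `extraction`. Default:
#'   positioning 1 s, insertion 2.80 s, repositioning 1.79 s, extraction
#'   0.91 s, retreat 0.5 s — so insertion occupies 50.9% and extraction
#'   16.5% of the bounded trial.
#' @param noise Named list of noise magnitudes: `positional` (Gaussian sd,
#'   m), `out_of_plane` (sinusoidal ripple amplitude, m), `radial_drift`
#'   (radial drift over the insertion, m), `force` (Gaussian sd, N). Set
#'   all to zero for noiseless trials.
#' @param peak_force Peak tissue-interaction force magnitude, N.
#'   Default 2.5.
#' @param exit_error Lateral offset between desired and actual exit
#'   points, m. Default 0.0015 (below the 2 mm exit marker radius).
#' @param tissue_pose List with `rotation` (3 x 3) and `shift` (3-vector)
#'   placing the tissue frame in the world. Default identity.
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @return An object of class `synthetic_trial_config`.
#' @export
trial_config <- function(needle_radius = 0.0187, arc_span = 5 * pi / 6,
                         sample_rate = 120,
                         subtask_schedule = default_schedule(),
                         noise = list(positional = 1.5e-4,
                                      out_of_plane = 4e-4,
                                      radial_drift = 3e-4,
                                      force = 4e-3),
                         peak_force = 2.5, exit_error = 1.5e-3,
                         tissue_pose = list(rotation = diag(3),
                                            shift = c(0, 0, 0)),
                         seed = NULL) {
  stopifnot(needle_radius > 0, sample_rate > 0)
  if (arc_span <= 0) stop("`arc_span` must be positive", call. = FALSE)
  subtask_schedule <- validate_schedule(subtask_schedule)
  nz <- list(positional = 0, out_of_plane = 0, radial_drift = 0, force = 0)
  nz[names(noise)] <- noise
  if (any(unlist(nz) < 0)) stop("noise magnitudes must be >= 0", call. = FALSE)
  structure(list(needle_radius = needle_radius, arc_span = arc_span,
                 sample_rate = sample_rate,
                 subtask_schedule = subtask_schedule, noise = nz,
                 peak_force = peak_force, exit_error = exit_error,
                 tissue_pose = tissue_pose, seed = seed),
            class = "synthetic_trial_config")
}

#' @rdname trial_config
#' @param correction Include a correction run (a second partial insertion
#'   near the entrance) in the default schedule.
#' @export
default_schedule <- function(correction = FALSE) {
  if (correction) {
    data.frame(label = c("outside", "insertion", "reposition", "correction",
                         "reposition", "extraction", "outside"),
               duration = c(1.0, 2.0, 0.9, 0.8, 0.9, 0.91, 0.5))
  } else {
    data.frame(label = c("outside", "insertion", "reposition", "extraction",
                         "outside"),
               duration = c(1.0, 2.80, 1.79, 0.91, 0.5))
  }
}

driving_labels <- c("insertion", "correction", "extraction")

validate_schedule <- function(schedule) {
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("label", "duration") %in% names(schedule)))
  schedule$label <- as.character(schedule$label)
  if (!all(schedule$label %in% subtask_levels))
    stop("unknown subtask label in schedule", call. = FALSE)
  if (any(schedule$duration <= 0))
    stop("schedule durations must be positive", call. = FALSE)
  drv <- schedule$label[schedule$label %in% driving_labels]
  if (length(drv) < 2 || drv[1] != "insertion" ||
      drv[length(drv)] != "extraction" ||
      any(drv[-c(1, length(drv))] != "correction") ||
      sum(drv == "insertion") != 1 || sum(drv == "extraction") != 1)
    stop("schedule must order driving subtasks as insertion, ",
         "[corrections], extraction", call. = FALSE)
  inner <- schedule$label[seq(which(schedule$label == "insertion"),
                              max(which(schedule$label == "extraction")))]
  if (any(inner == "outside"))
    stop("'outside' phases may only lead or trail the schedule", call. = FALSE)
  schedule
}

# Arc geometry in the tissue surface frame. The insertion plane is vertical
# and contains the horizontal x-y diagonal (so the two horizontal force
# components are correlated, as observed in correctly performed trials).
arc_geometry <- function(config) {
  R <- config$needle_radius
  span <- config$arc_span
  dhat <- c(1, 1, 0) / sqrt(2)          # chord direction
  center <- c(0, 0, R * cos(span / 2))  # circle center, above the surface
  pts <- function(frac) {
    phi <- -span / 2 + frac * span
    cbind(R * sin(phi) * dhat[1], R * sin(phi) * dhat[2],
          center[3] - R * cos(phi))
  }
  list(radius = R, span = span, dhat = dhat, center = center, points = pts,
       rot_axis = c(-dhat[2], dhat[1], 0),
       entrance = as.numeric(pts(0)), exit = as.numeric(pts(1)))
}

# Default tissue geometry consistent with a trial configuration.
default_geometry <- function(config) {
  arc <- arc_geometry(config)
  actual_exit <- arc$exit
  perp <- c(-arc$dhat[2], arc$dhat[1], 0)
  desired <- actual_exit + config$exit_error * perp
  geom <- tissue_geometry(entrance_point = arc$entrance,
                          desired_exit = desired,
                          actual_exit = actual_exit)
  pose <- config$tissue_pose
  transform_geometry(geom, pose$rotation, pose$shift)
}

#' Generate an ideal (noiseless) insertion trajectory
#'
#' The tooltip path lies exactly on a circle of radius `needle_radius` in
#' the insertion plane, swept at constant angular velocity over
#' `arc_span`; the tooltip orientation rotates with the arc tangent, and
#' timestamps are uniform at `sample_rate`. Forces and torques are zero:
#' this is the reference trajectory downstream fits should recover
#' perfectly (zero circle and plane deviation).
#'
#' @param config A [trial_config()].
#' @param duration Sweep duration, s. Default: the schedule's insertion
#'   duration.
#' @return A [trial_recording()].
#' @export
generate_ideal_insertion <- function(config = trial_config(),
                                     duration = NULL) {
  stopifnot(inherits(config, "synthetic_trial_config"))
  duration <- duration %||%
    config$subtask_schedule$duration[config$subtask_schedule$label == "insertion"][1]
  arc <- arc_geometry(config)
  t <- seq(0, duration, by = 1 / config$sample_rate)
  frac <- t / duration
  pos <- arc$points(frac)
  phi <- -arc$span / 2 + frac * arc$span
  q <- quat_from_axis_angle(arc$rot_axis, phi)
  z3 <- matrix(0, length(t), 3)
  trial <- trial_recording(t, pos, q, rep(0.1, length(t)), z3, z3,
                          meta = list(setup = "open", rate = config$sample_rate,
                                      synthetic = TRUE))
  pose <- config$tissue_pose
  rigid_transform_trial(trial, pose$rotation, pose$shift)
}

# Smooth 0 -> 1 easing (zero slope at both ends).
ease <- function(s) (1 - cos(pi * clamp(s, 0, 1))) / 2

# Allocate arc fractions [lo, hi] to the driving runs of a schedule.
allocate_arc <- function(labels) {
  drv <- which(labels %in% driving_labels)
  k <- length(drv)
  out <- vector("list", length(labels))
  if (k == 1) { out[[drv]] <- c(0, 1); return(out) }
  ncor <- k - 2
  if (ncor == 0) {
    out[[drv[1]]] <- c(0, 0.70)
    out[[drv[2]]] <- c(0.70, 1)
  } else {
    out[[drv[1]]] <- c(0, 0.50)
    lo <- 0.30
    for (i in seq_len(ncor)) {
      hi <- lo + 0.25 / ncor
      out[[drv[1 + i]]] <- c(lo, hi)
      lo <- hi
    }
    out[[drv[k]]] <- c(lo, 1)
  }
  out
}

#' Generate a synthetic needle-driving trial
#'
#' Builds one complete trial following the configured subtask schedule:
#' the tooltip approaches from outside the tissue contour, drives the
#' needle along its arc (gripper closed, force above the sensor noise
#' threshold), lifts off between driving runs (gripper open, only small
#' transient forces), extracts, and retreats. The force pattern follows
#' the phase structure of a correctly performed trial: correlated
#' horizontal components during insertion, a mid-insertion sign reversal
#' of the vertical component, occasional small forces during
#' repositioning, and a vertical-dominant extraction.
#'
#' @param config A [trial_config()].
#' @param geom A [tissue_geometry()]; a geometry consistent with the
#'   configuration is built when `NULL`.
#' @param threshold Force noise threshold used to shape driving-phase
#'   force floors, N. Default 0.06.
#' @return A list with the raw `trial` ([trial_recording()]), the `geom`,
#'   the ground-truth per-sample `truth` labels (factor), and the realized
#'   `schedule` with absolute start/end times.
#' @export
generate_trial <- function(config = trial_config(), geom = NULL,
                           threshold = 0.06) {
  stopifnot(inherits(config, "synthetic_trial_config"))
  sched <- config$subtask_schedule
  if (is.null(geom)) geom <- default_geometry(config)
  with_seed(config$seed, generate_trial_impl(config, geom, sched, threshold))
}

generate_trial_impl <- function(config, geom, sched, threshold) {
  rate <- config$sample_rate
  arc <- arc_geometry(config)
  t_edges <- cumsum(c(0, sched$duration))
  total <- t_edges[length(t_edges)]
  t <- seq(0, total, by = 1 / rate)
  n <- length(t)
  phase_id <- clamp(findInterval(t, t_edges, rightmost.closed = TRUE),
                    1, nrow(sched))
  labels <- sched$label[phase_id]
  u <- (t - t_edges[phase_id]) / sched$duration[phase_id]   # within-phase 0..1

  arc_alloc <- allocate_arc(sched$label)
  # arc fraction per sample: progresses during driving, interpolates during
  # repositioning, holds outside
  frac <- numeric(n)
  last_frac <- 0
  for (k in seq_len(nrow(sched))) {
    sel <- phase_id == k
    if (!any(sel)) next
    lab <- sched$label[k]
    if (lab %in% driving_labels) {
      rng <- arc_alloc[[k]]
      frac[sel] <- rng[1] + (rng[2] - rng[1]) * ease(u[sel])
      last_frac <- rng[2]
    } else if (lab == "reposition") {
      nxt <- which(sched$label %in% driving_labels &
                     seq_len(nrow(sched)) > k)
      target <- if (length(nxt)) arc_alloc[[nxt[1]]][1] else last_frac
      frac[sel] <- last_frac + (target - last_frac) * ease(u[sel])
    } else {
      nxt <- which(sched$label %in% driving_labels &
                     seq_len(nrow(sched)) > k)
      frac[sel] <- if (length(nxt)) 0 else last_frac
    }
  }

  pos <- arc$points(frac)
  # lift-off bump during repositioning; approach/retreat outside the contour
  lift <- 0.012
  away <- 0.055
  for (k in seq_len(nrow(sched))) {
    sel <- phase_id == k
    if (!any(sel)) next
    lab <- sched$label[k]
    if (lab == "reposition") {
      pos[sel, 3] <- pos[sel, 3] + lift * sin(pi * u[sel])
    } else if (lab == "outside") {
      leading <- any(which(sel) < which(labels %in% driving_labels)[1])
      anchor <- if (leading) arc$entrance else arc$exit
      dir_out <- if (leading) -arc$dhat else arc$dhat
      s <- if (leading) 1 - ease(u[sel]) else ease(u[sel])
      pos[sel, ] <- matrix(anchor, sum(sel), 3, byrow = TRUE) +
        outer(s, dir_out * away) + cbind(0, 0, 0.02 * s)
    }
  }

  # noise: white positional jitter + out-of-plane ripple + radial drift
  nz <- config$noise
  perp <- c(-arc$dhat[2], arc$dhat[1], 0)
  drv <- labels %in% driving_labels
  if (nz$out_of_plane > 0)
    pos <- pos + outer(nz$out_of_plane * sin(2 * pi * 1.3 * t) * drv, perp)
  if (nz$radial_drift > 0) {
    radial <- (pos - matrix(arc$center, n, 3, byrow = TRUE))
    rn <- row_norms(radial)
    ok <- rn > 1e-9 & drv
    pos[ok, ] <- pos[ok, ] +
      radial[ok, , drop = FALSE] / rn[ok] * (nz$radial_drift * frac[ok])
  }
  if (nz$positional > 0)
    pos <- pos + matrix(rnorm(3 * n, 0, nz$positional), n, 3)

  # orientation follows the arc tangent
  phi <- -arc$span / 2 + frac * arc$span
  q <- quat_from_axis_angle(arc$rot_axis, phi)

  # gripper: closed while holding the needle (positioning + driving), open
  # while repositioning and retreating
  grip <- ifelse(labels == "reposition", 0.8, 0.1)
  trailing_out <- labels == "outside" &
    seq_len(n) > max(which(labels %in% driving_labels))
  grip[trailing_out] <- 0.8

  frc <- synth_forces(labels, u, config, threshold, arc)
  if (nz$force > 0) frc <- frc + matrix(rnorm(3 * n, 0, nz$force), n, 3)

  trq <- matrix(0, n, 3)
  trq[drv, 3] <- 0.15 * config$peak_force * 0.02 * sin(2 * pi * 1.1 * u[drv])
  trq[drv, 1] <- 0.05 * config$peak_force * 0.02 * sin(2 * pi * 0.9 * u[drv])
  if (nz$force > 0) trq <- trq + matrix(rnorm(3 * n, 0, nz$force * 0.02), n, 3)

  meta <- list(setup = if (rate >= 300) "teleop" else "open", rate = rate,
               synthetic = TRUE)
  trial <- trial_recording(t, pos, q, grip, frc, trq, meta)
  pose <- config$tissue_pose
  trial <- rigid_transform_trial(trial, pose$rotation, pose$shift)

  sched_abs <- cbind(sched, t_start = t_edges[-length(t_edges)],
                     t_end = t_edges[-1])
  list(trial = trial, geom = geom,
       truth = factor(labels, levels = subtask_levels),
       schedule = sched_abs)
}

# Phase-structured tissue-interaction forces (surface frame).
synth_forces <- function(labels, u, config, threshold, arc) {
  n <- length(labels)
  frc <- matrix(0, n, 3)
  peak <- config$peak_force
  floor_f <- 2 * threshold                # driving force floor, above th
  dhat <- arc$dhat
  for (lab in unique(labels)) {
    sel <- labels == lab
    uu <- u[sel]
    if (lab %in% c("insertion", "correction")) {
      scale <- if (lab == "insertion") 1 else 0.6
      mag_h <- floor_f + (scale * peak - floor_f) * sin(pi * uu)
      frc[sel, 1] <- mag_h * dhat[1]
      frc[sel, 2] <- mag_h * dhat[2]
      frc[sel, 3] <- -0.5 * scale * peak * cos(pi * uu) * sin(pi * uu)^0.5
    } else if (lab == "extraction") {
      mag_v <- floor_f + (0.9 * peak - floor_f) * sin(pi * uu)
      frc[sel, 3] <- mag_v
      frc[sel, 1] <- 0.3 * mag_v * (1 - uu) * dhat[1]
      frc[sel, 2] <- 0.3 * mag_v * (1 - uu) * dhat[2]
    } else if (lab == "reposition") {
      frc[sel, 1] <- 0.018 * sin(2 * pi * 2.7 * uu)
      frc[sel, 2] <- 0.014 * sin(2 * pi * 3.1 * uu + 1)
      frc[sel, 3] <- -0.010 * sin(2 * pi * 2.2 * uu + 0.4)
    }
  }
  frc
}

#' Ground-truth subtask labels at arbitrary timestamps
#'
#' Evaluates a realized schedule (from [generate_trial()]) at new
#' timestamps, e.g. after resampling the trial to a uniform rate.
#'
#' @param schedule The `schedule` element returned by [generate_trial()].
#' @param t Timestamps, s.
#' @return Factor of subtask labels.
#' @export
schedule_truth_labels <- function(schedule, t) {
  edges <- c(schedule$t_start, schedule$t_end[nrow(schedule)])
  idx <- clamp(findInterval(t, edges, rightmost.closed = TRUE),
               1, nrow(schedule))
  factor(schedule$label[idx], levels = subtask_levels)
}
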