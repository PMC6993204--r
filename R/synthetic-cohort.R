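#' Cohort configuration
#'
#' Design of a synthetic cohort mirroring the experimental protocol: three
#' feedback groups (no feedback NF, position exchange PE, direct feedback
#' DF) of `n_per_group` participants, each performing
#' `sum(blocks) * trials_per_block` trials split into an open baseline
#' phase, a teleoperation phase, and a second open phase.
#'
#' @param n_per_group Participants per feedback condition (>= 2).
#'   Default 10.
#' @param conditions Feedback condition labels. Default `c("NF", "PE",
#'   "DF")`.
#' @param trials_per_block Trials per block. Default 10.
#' @param blocks Named block counts per phase,
#'   `c(open1 = 4, tele = 6, open2 = 2)` by default (120 trials total).
#' @param effect_model Per-metric effect model, see
#'   [default_effect_model()].
#' @param learning_scale Named multiplier per condition applied to the
#'   learning effects (all 1 by default: no between-condition difference).
#' @param seed Integer seed for reproducibility.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 10, conditions = c("NF", "PE", "DF"),
                          trials_per_block = 10,
                          blocks = c(open1 = 4, tele = 6, open2 = 2),
                          effect_model = default_effect_model(),
                          learning_scale = NULL, seed = NULL) {
  if (n_per_group < 2)
    stop("`n_per_group` must be >= 2 (contrasts are undefined otherwise)",
         call. = FALSE)
  stopifnot(trials_per_block >= 1, length(blocks) == 3,
            all(names(blocks) == c("open1", "tele", "open2")),
            all(blocks >= 1))
  if (is.null(learning_scale))
    learning_scale <- stats::setNames(rep(1, length(conditions)), conditions)
  structure(list(n_per_group = n_per_group, conditions = conditions,
                 trials_per_block = trials_per_block, blocks = blocks,
                 effect_model = effect_model,
                 learning_scale = learning_scale, seed = seed),
            class = "cohort_config")
}

#' Default per-metric effect model
#'
#' The generative model behind [generate_cohort()]: each metric has a
#' baseline level, log-normal (for strictly positive metrics) or Gaussian
#' (for sign-carrying metrics) trial-to-trial and between-participant
#' variability, a teleoperation offset, and a learning effect. The
#' learning effect elevates the metric at the start of teleoperation and
#' decays linearly to zero by its end, so the learning contrast
#' (tele late - tele early) is negative for improving metrics. Additive
#' effects act on the log scale for positive metrics, keeping them
#' positive. Baselines and effect magnitudes are set to the order of
#' magnitude of values observed for inexperienced operators in this task.
#'
#' @param learning_scale Scalar multiplier on every learning effect
#'   (0 gives a null cohort). Default 1.
#' @return Named list (one entry per metric) of model parameter lists:
#'   `baseline`, `trial_sd`, `participant_sd`, `learning`, `tele_offset`,
#'   `log_scale`, `teleop_only`.
#' @export
default_effect_model <- function(learning_scale = 1) {
  m <- function(baseline, trial_sd, participant_sd, learning, tele_offset,
                log_scale = TRUE, teleop_only = FALSE) {
    list(baseline = baseline, trial_sd = trial_sd,
         participant_sd = participant_sd,
         learning = learning * learning_scale, tele_offset = tele_offset,
         log_scale = log_scale, teleop_only = teleop_only)
  }
  list(
    completion_time        = m(8,     0.18, 0.15, 0.30, 0.63),
    exit_point_error       = m(0.002, 0.35, 0.25, 0.05, 0,    teleop_only = TRUE),
    total_normalized_force = m(8,     0.25, 0.20, 0.12, 0.20, teleop_only = TRUE),
    max_force              = m(2.5,   0.20, 0.20, 0,    0.10),
    max_torque_z           = m(0.03,  0.30, 0.25, 0.15, 0.20),
    force_consistency      = m(2000,  0.50, 0.40, 0.50, 0.40),
    path_length            = m(0.12,  0.15, 0.12, 0.15, 0.10),
    circle_deviation       = m(8e-6,  0.50, 0.40, 0.35, 0.30),
    plane_deviation        = m(5e-6,  0.50, 0.40, 0.35, 0.30),
    angular_path           = m(60,    0.20, 0.20, 0,    0),
    trajectory_consistency = m(0.05,  0.50, 0.40, 0.40, 0.30),
    powerlaw_alpha         = m(0.12,  0.15, 0.12, 0,    -0.10),
    powerlaw_beta          = m(-0.30, 0.04, 0.03, 0.015 , 0, log_scale = FALSE),
    powerlaw_gamma         = m(-0.14, 0.04, 0.03, 0.015 , 0, log_scale = FALSE),
    log_jerk               = m(2.2,   0.15, 0.12, 0.05, -1.20, log_scale = FALSE)
  )
}

#' Generate a synthetic cohort dataset
#'
#' Draws per-trial metric values for a full cohort from the configured
#' effect model: participants are assigned to exactly one feedback
#' condition, trials carry phase / block / trial annotations, and each
#' participant's metric levels drift across the teleoperation phase
#' according to the injected learning effects. Metrics available only in
#' teleoperation are `NA` in the open phases. Output is deterministic
#' under a fixed seed.
#'
#' To turn selected rows into full raw recordings (for the preprocessing /
#' segmentation / metric stages), see [materialize_trial()].
#'
#' @param cfg A [cohort_config()].
#' @return A [tibble::tibble()] with columns `participant`, `condition`,
#'   `phase`, `block`, `trial` (1-based within participant),
#'   `trial_in_phase`, and one column per metric.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  tpb <- cfg$trials_per_block
  phases <- rep(names(cfg$blocks), cfg$blocks * tpb)
  blocks <- rep(seq_len(sum(cfg$blocks)), each = tpb)
  n_trials <- length(phases)
  tele_idx <- which(phases == "tele")
  n_tele <- length(tele_idx)
  trial_in_phase <- stats::ave(seq_len(n_trials), phases,
                               FUN = seq_along)

  participants <- sprintf("P%02d", seq_len(cfg$n_per_group *
                                             length(cfg$conditions)))
  condition <- rep(cfg$conditions, each = cfg$n_per_group)

  rows <- vector("list", length(participants))
  for (p in seq_along(participants)) {
    cond <- condition[p]
    lscale <- cfg$learning_scale[[cond]]
    vals <- lapply(cfg$effect_model, function(em) {
      bias <- rnorm(1, 0, em$participant_sd)
      # learning elevation: +learning at tele start, linearly to 0 at end
      elev <- numeric(n_trials)
      if (n_tele > 1)
        elev[tele_idx] <- em$learning * lscale *
          (1 - (seq_len(n_tele) - 1) / (n_tele - 1))
      off <- ifelse(phases == "tele", em$tele_offset, 0)
      eps <- rnorm(n_trials, 0, em$trial_sd)
      v <- if (em$log_scale)
        exp(log(em$baseline) + bias + off + elev + eps)
      else em$baseline + bias + off + elev + eps
      if (em$teleop_only) v[phases != "tele"] <- NA_real_
      v
    })
    rows[[p]] <- tibble::tibble(participant = participants[p],
                                condition = cond, phase = phases,
                                block = blocks, trial = seq_len(n_trials),
                                trial_in_phase = trial_in_phase,
                                !!!vals)
  }
  out <- do.call(rbind, rows)
  out$condition <- factor(out$condition, levels = cfg$conditions)
  out$phase <- factor(out$phase, levels = names(cfg$blocks))
  out
}

#' Materialize a cohort row as a raw trial recording
#'
#' Builds a full synthetic recording whose scale parameters follow one
#' cohort row: the subtask schedule is scaled so the bounded trial lasts
#' about the row's completion time, the peak force follows the row's max
#' force, and the native sampling rate follows the row's setup (120 Hz
#' open, 500 Hz teleoperation).
#'
#' @param cohort A [generate_cohort()] table.
#' @param i Row index to materialize.
#' @param base_config Template [trial_config()].
#' @param seed Integer seed; by default derived from the row index.
#' @return As [generate_trial()]: list with `trial`, `geom`, `truth`,
#'   `schedule`.
#' @export
materialize_trial <- function(cohort, i, base_config = trial_config(),
                              seed = NULL) {
  row <- cohort[i, ]
  cfg <- base_config
  sched <- cfg$subtask_schedule
  drv <- sched$label != "outside"
  target <- row$completion_time
  if (is.finite(target) && target > 0.5)
    sched$duration[drv] <- sched$duration[drv] * target / sum(sched$duration[drv])
  cfg$subtask_schedule <- sched
  if (is.finite(row$max_force)) cfg$peak_force <- row$max_force
  cfg$sample_rate <- if (row$phase == "tele") 500 else 120
  cfg$seed <- seed %||% (i %% .Machine$integer.max)
  res <- generate_trial(cfg)
  res$trial$meta$participant <- as.character(row$participant)
  res$trial$meta$condition <- as.character(row$condition)
  res$trial$meta$phase <- as.character(row$phase)
  res$trial$meta$block <- row$block
  res$trial$meta$trial <- row$trial
  res
}
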