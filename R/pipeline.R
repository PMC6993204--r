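#' Pipeline configuration
#'
#' Validated bundle of every tunable parameter of the analysis pipeline,
#' with defaults matching the experimental analysis: 100 Hz target rate,
#' 10 Hz 2nd-order zero-phase Butterworth filtering, 0.06 N force noise
#' threshold, blocks of 5 trials for the stage medians.
#'
#' @param target_rate Uniform resampling rate, Hz. Default 100.
#' @param cutoff Low-pass cutoff, Hz. Default 10.
#' @param order Filter order. Default 2.
#' @param threshold Force noise threshold, N. Default 0.06.
#' @param gripper_closed Gripper-closed threshold. Default 0.5.
#' @param segment Subtask scored by the metric suite. Default
#'   `"insertion"`.
#' @param circle_radius Nominal needle radius for the circle-deviation
#'   normalizer, or `NULL` (default) for the fitted radius.
#' @param block Trials per stage block. Default 5.
#' @param n_profiles Profiles per consistency computation. Default 5.
#' @param bootstrap_B Bootstrap resamples. Default 2000.
#' @param conf Confidence level. Default 0.95.
#' @param seed Seed for stochastic stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(target_rate = 100, cutoff = 10, order = 2,
                            threshold = 0.06, gripper_closed = 0.5,
                            segment = "insertion", circle_radius = NULL,
                            block = 5, n_profiles = 5, bootstrap_B = 2000,
                            conf = 0.95, seed = NULL) {
  stopifnot(target_rate > 0, cutoff > 0, cutoff < target_rate / 2,
            order >= 1, threshold >= 0, block >= 1, n_profiles >= 2,
            conf > 0, conf < 1)
  structure(list(target_rate = target_rate, cutoff = cutoff, order = order,
                 threshold = threshold, gripper_closed = gripper_closed,
                 segment = segment, circle_radius = circle_radius,
                 block = block, n_profiles = n_profiles,
                 bootstrap_B = bootstrap_B, conf = conf, seed = seed),
            class = "pipeline_config")
}

trial_columns <- c("t", "px", "py", "pz", "qw", "qx", "qy", "qz", "grip",
                   "fx", "fy", "fz", "tqx", "tqy", "tqz")

#' Read / write trial files
#'
#' A trial is stored as a CSV with one row per sample and columns
#' `t, px, py, pz, qw, qx, qy, qz, grip, fx, fy, fz, tqx, tqy, tqz`
#' (SI units, w-first quaternions), plus a JSON sidecar `<path>.json`
#' holding the metadata. The round trip is lossless to the printed
#' precision (17 significant digits).
#'
#' @param trial A [trial_recording()].
#' @param path CSV file path.
#' @return `read_trial` returns a [trial_recording()]; `write_trial`
#'   returns `path` invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "trial_recording"))
  df <- data.frame(trial$t, trial$position, trial$quaternion, trial$gripper,
                   trial$force, trial$torque)
  names(df) <- trial_columns
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(trial$meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(trial_columns, names(df))
  if (length(missing_cols))
    stop("malformed trial file, missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  trial_recording(df$t, as.matrix(df[, c("px", "py", "pz")]),
                  as.matrix(df[, c("qw", "qx", "qy", "qz")]), df$grip,
                  as.matrix(df[, c("fx", "fy", "fz")]),
                  as.matrix(df[, c("tqx", "tqy", "tqz")]), meta)
}

#' Run the full analysis pipeline on a set of raw trials
#'
#' Orchestrates the stages end to end: preprocess every raw trial to the
#' uniform rate, detect bounds and classify subtasks, score the per-trial
#' metric suite on the configured subtask, compute the DTW consistency
#' metrics per stage block of trials, and run the contrast statistics.
#' Per-trial failures are quarantined and logged, not fatal.
#'
#' @param trials List of entries, each a list with `trial` (a raw
#'   [trial_recording()] whose `meta` carries `participant`, `condition`,
#'   `phase`, `block`, `trial`) and `geom` (a [tissue_geometry()]), as
#'   produced by [materialize_trial()].
#' @param config A [pipeline_config()].
#' @return List with `trial_metrics` (per-trial tibble), `tables` (a
#'   `contrast_tables` object, when enough stages are available),
#'   `stage_consistency`, and `log` (per-trial status tibble).
#' @export
run_pipeline <- function(trials, config = pipeline_config()) {
  stopifnot(length(trials) > 0)
  rows <- list(); logs <- list()
  profiles <- list()   # per processed trial: insertion force/position
  for (k in seq_along(trials)) {
    entry <- trials[[k]]
    res <- tryCatch({
      u <- preprocess_trial(entry$trial, config$target_rate, config$cutoff,
                            config$order)
      seg <- classify_segments(u, entry$geom, config$threshold,
                               gripper_closed = config$gripper_closed)
      mv <- compute_trial_metrics(seg, entry$geom, config$segment,
                                  config$circle_radius)
      idx <- segment_indices(seg, config$segment)
      list(mv = mv, force = u$force[idx, , drop = FALSE],
           pos = u$position[idx, , drop = FALSE])
    }, error = function(e) e)
    meta <- entry$trial$meta
    id <- tibble::tibble(participant = meta$participant %||% NA_character_,
                         condition = meta$condition %||% NA_character_,
                         phase = meta$phase %||% NA_character_,
                         block = meta$block %||% NA_integer_,
                         trial = meta$trial %||% k)
    if (inherits(res, "error")) {
      logs[[k]] <- cbind(id, tibble::tibble(status = "quarantined",
                                            message = conditionMessage(res)))
      next
    }
    logs[[k]] <- cbind(id, tibble::tibble(status = "ok", message = ""))
    rows[[k]] <- cbind(id, res$mv)
    profiles[[k]] <- list(id = id, force = res$force, pos = res$pos)
  }
  trial_metrics <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  log <- do.call(rbind, logs)
  if (is.null(trial_metrics)) stop("no trial could be processed", call. = FALSE)

  stage_consistency <- stage_consistency_table(profiles, trial_metrics,
                                               config)
  tables <- tryCatch(
    run_full_analysis(merge_stage_consistency(trial_metrics,
                                              stage_consistency),
                      block = config$block, B = config$bootstrap_B,
                      conf = config$conf, seed = config$seed),
    error = function(e) NULL)
  list(trial_metrics = trial_metrics, tables = tables,
       stage_consistency = stage_consistency, log = log)
}

# DTW consistency of each analysis stage's block of insertion profiles.
stage_consistency_table <- function(profiles, trial_metrics, config) {
  profiles <- profiles[!vapply(profiles, is.null, TRUE)]
  if (!length(profiles)) return(NULL)
  ids <- do.call(rbind, lapply(profiles, function(p) p$id))
  out <- list()
  stages <- stage_definitions(config$n_profiles)
  for (p in unique(ids$participant)) {
    for (sname in names(stages)) {
      st <- stages[[sname]]
      sel <- which(ids$participant == p & ids$phase == st$phase)
      sel <- sel[order(ids$trial[sel])]
      if (length(sel) < st$k) next
      sel <- if (st$side == "first") utils::head(sel, st$k)
             else utils::tail(sel, st$k)
      fprof <- lapply(profiles[sel], `[[`, "force")
      xprof <- lapply(profiles[sel], `[[`, "pos")
      out[[length(out) + 1]] <- tibble::tibble(
        participant = p, condition = ids$condition[sel[1]], stage = sname,
        force_consistency = dtw_consistency(fprof),
        trajectory_consistency = dtw_consistency(xprof))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Inject stage-level consistency values into the per-trial table so that
# the block medians reproduce them: every trial of the stage's block gets
# the stage value (its median is the value itself).
merge_stage_consistency <- function(trial_metrics, stage_consistency) {
  if (is.null(stage_consistency)) return(trial_metrics)
  tm <- trial_metrics
  stages <- stage_definitions(5)
  for (r in seq_len(nrow(stage_consistency))) {
    sc <- stage_consistency[r, ]
    st <- stages[[sc$stage]]
    sel <- which(tm$participant == sc$participant & tm$phase == st$phase)
    sel <- sel[order(tm$trial[sel])]
    sel <- if (st$side == "first") utils::head(sel, st$k)
           else utils::tail(sel, st$k)
    tm$force_consistency[sel] <- sc$force_consistency
    tm$trajectory_consistency[sel] <- sc$trajectory_consistency
  }
  tm
}
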