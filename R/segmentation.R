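#' Detect trial bounds from force and position
#'
#' A trial starts at the first interaction of the needle with the tissue and
#' ends at the last one. Both are detected as the first / last sample at
#' which the force magnitude exceeds the sensor noise threshold *and* the
#' tooltip's projection onto the tissue surface lies inside the tissue
#' contour (so that accidental contact with the fixture is excluded). Both
#' conditions are required simultaneously.
#'
#' Indices are 0-based and inclusive throughout the segmentation interfaces.
#'
#' @param trial A preprocessed uniform [trial_recording()].
#' @param geom A [tissue_geometry()].
#' @param threshold Force noise threshold, N. Default 0.06.
#' @return Integer vector `c(i_start, i_end)` of 0-based sample indices.
#' @export
detect_trial_bounds <- function(trial, geom, threshold = 0.06) {
  fmag <- row_norms(trial$force)
  xy <- surface_coords(trial$position, geom)[, 1:2, drop = FALSE]
  ok <- fmag > threshold & point_in_contour(xy, geom)
  if (!any(ok)) stop("no trial detected: no sample exceeds the force ",
                     "threshold inside the tissue contour", call. = FALSE)
  idx <- which(ok)
  c(i_start = idx[1] - 1L, i_end = idx[length(idx)] - 1L)
}

#' Label needle-driving samples
#'
#' A sample belongs to a needle-driving segment (insertion, correction or
#' extraction) when the gripper is closed and the tissue-interaction force
#' is above the noise threshold. The mask is false outside the trial bounds
#' by contract.
#'
#' @inheritParams detect_trial_bounds
#' @param bounds Trial bounds as returned by [detect_trial_bounds()];
#'   computed when `NULL`.
#' @param gripper_closed Gripper channel values at or below this value count
#'   as closed. Default 0.5.
#' @return Logical vector, one entry per sample.
#' @export
label_driving_samples <- function(trial, geom, threshold = 0.06,
                                  bounds = NULL, gripper_closed = 0.5) {
  if (is.null(bounds)) bounds <- detect_trial_bounds(trial, geom, threshold)
  fmag <- row_norms(trial$force)
  mask <- trial$gripper <= gripper_closed & fmag > threshold
  n <- n_samples(trial)
  inb <- seq_len(n) - 1L >= bounds[1] & seq_len(n) - 1L <= bounds[2]
  mask & inb
}

subtask_levels <- c("outside", "insertion", "correction", "reposition",
                    "extraction")

# Maximal runs of TRUE in a logical vector: data.frame(start, end), 1-based.
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Classify samples into needle-driving subtasks
#'
#' Orders the maximal runs of the driving mask in time and labels them: the
#' first run is the insertion, the last run the extraction, and intermediate
#' runs are corrections when their mean tooltip position (projected onto the
#' tissue surface) is Euclidean-closer to the needle entrance point than to
#' the exit point, extraction-class otherwise. Gaps between runs inside the
#' trial bounds are repositioning; samples outside the bounds are `outside`.
#' A single continuous run is labeled insertion.
#'
#' @inheritParams label_driving_samples
#' @param mask Driving mask from [label_driving_samples()]; computed when
#'   `NULL`.
#' @return An object of class `segmented_trial`: list with the `trial`,
#'   0-based inclusive `bounds`, and a per-sample factor `labels`.
#' @export
classify_segments <- function(trial, geom, threshold = 0.06, mask = NULL,
                              bounds = NULL, gripper_closed = 0.5) {
  if (is.null(bounds)) bounds <- detect_trial_bounds(trial, geom, threshold)
  if (is.null(mask))
    mask <- label_driving_samples(trial, geom, threshold, bounds,
                                  gripper_closed)
  runs <- runs_of(mask)
  if (nrow(runs) == 0) stop("no needle-driving samples found", call. = FALSE)

  exit_pt <- geom$actual_exit %||% geom$desired_exit
  ent_xy <- surface_coords(matrix(geom$entrance_point, 1), geom)[, 1:2]
  exit_xy <- surface_coords(matrix(exit_pt, 1), geom)[, 1:2]

  run_label <- character(nrow(runs))
  run_label[1] <- "insertion"
  if (nrow(runs) > 1) run_label[nrow(runs)] <- "extraction"
  if (nrow(runs) > 2) {
    for (k in 2:(nrow(runs) - 1)) {
      xy <- surface_coords(trial$position[runs$start[k]:runs$end[k], ,
                                          drop = FALSE], geom)[, 1:2,
                                                               drop = FALSE]
      ctr <- colMeans(xy)
      run_label[k] <- if (sum((ctr - ent_xy)^2) < sum((ctr - exit_xy)^2))
        "correction" else "extraction"
    }
  }

  n <- n_samples(trial)
  labels <- rep("outside", n)
  inb <- (bounds[1] + 1L):(bounds[2] + 1L)
  labels[inb] <- "reposition"
  for (k in seq_len(nrow(runs)))
    labels[runs$start[k]:runs$end[k]] <- run_label[k]
  structure(list(trial = trial, bounds = bounds,
                 labels = factor(labels, levels = subtask_levels)),
            class = "segmented_trial")
}

#' @export
print.segmented_trial <- function(x, ...) {
  cat(sprintf("<segmented_trial> bounds [%d, %d] of %d samples\n",
              x$bounds[1], x$bounds[2], n_samples(x$trial)))
  print(table(x$labels))
  invisible(x)
}

#' Relative subtask durations
#'
#' Fraction of the bounded trial duration spent in each subtask label.
#' Fractions are in `[0, 1]` and sum to 1 over the labels inside the trial
#' bounds.
#'
#' @param seg A [classify_segments()] result.
#' @return Named numeric vector of fractions for insertion, correction,
#'   reposition and extraction.
#' @export
relative_durations <- function(seg) {
  stopifnot(inherits(seg, "segmented_trial"))
  inb <- (seg$bounds[1] + 1L):(seg$bounds[2] + 1L)
  tab <- table(factor(seg$labels[inb],
                      levels = setdiff(subtask_levels, "outside")))
  stats::setNames(as.numeric(tab) / length(inb), names(tab))
}

#' Apply manually validated bounds
#'
#' Replaces automatically detected bounds with externally validated ones
#' (e.g. from a review of force profiles and trial video) and relabels the
#' subtasks accordingly.
#'
#' @inheritParams classify_segments
#' @param bounds Corrected 0-based inclusive bounds.
#' @return A `segmented_trial` using the supplied bounds.
#' @export
override_bounds <- function(trial, geom, bounds, threshold = 0.06,
                            gripper_closed = 0.5) {
  stopifnot(length(bounds) == 2, bounds[1] >= 0,
            bounds[2] < n_samples(trial), bounds[1] <= bounds[2])
  classify_segments(trial, geom, threshold, mask = NULL,
                    bounds = as.integer(bounds),
                    gripper_closed = gripper_closed)
}
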