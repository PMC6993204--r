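#' Dynamic time warping alignment of two profiles
#'
#' Aligns two multichannel time series with dynamic time warping using
#' squared-Euclidean local cost and the symmetric step pattern (no window).
#'
#' @param a,b Numeric matrices (samples x channels) or vectors.
#' @return A list with `distance` (accumulated squared-Euclidean cost) and
#'   the warping path `index1`, `index2` (1-based).
#' @export
dtw_align <- function(a, b) {
  a <- if (is.null(dim(a))) matrix(as.numeric(a), ncol = 1) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(as.numeric(b), ncol = 1) else as.matrix(b)
  dtw_core(a, b)
}

# Warp `prof` onto the time base of `ref` along the DTW path: samples of
# `prof` matched to the same reference index are averaged.
dtw_warp_onto <- function(ref, prof) {
  al <- dtw_align(ref, prof)
  pm <- prof[al$index2, , drop = FALSE]
  counts <- tabulate(al$index1, nbins = nrow(ref))
  acc <- rowsum(pm, group = al$index1, reorder = TRUE)
  acc / counts
}

#' DTW-aligned consistency of repeated profiles
#'
#' Consistency of a set of repeated force or position profiles: the
#' profiles are aligned by dynamic time warping to a common reference (the
#' medoid — the profile minimizing the summed DTW cost to the others), the
#' pointwise mean profile is formed on the reference time base, and the
#' metric is the mean over profiles of the summed squared Euclidean
#' distances to that mean profile:
#' `(1/N_t) * sum_i sum_n |p_i(n) - mean(n)|^2`.
#' Zero iff all profiles are identical after alignment; lower is more
#' consistent.
#'
#' @param profiles List of `N_t >= 2` numeric matrices (samples x channels)
#'   or vectors; the analysis uses blocks of 5 trials.
#' @param align `"dtw"` (default) or `"none"` (pointwise, requires equal
#'   lengths; provided for comparison).
#' @return Squared units of the profile channel (N^2 for forces, m^2 for
#'   positions).
#' @export
dtw_consistency <- function(profiles, align = c("dtw", "none")) {
  align <- match.arg(align)
  stopifnot(is.list(profiles), length(profiles) >= 2)
  profiles <- lapply(profiles, function(p)
    if (is.null(dim(p))) matrix(as.numeric(p), ncol = 1) else as.matrix(p))
  if (any(vapply(profiles, nrow, 1L) < 2))
    stop("profiles must have length >= 2", call. = FALSE)
  nt <- length(profiles)

  if (align == "none") {
    lens <- vapply(profiles, nrow, 1L)
    if (length(unique(lens)) != 1)
      stop("align = 'none' requires equal-length profiles", call. = FALSE)
    warped <- profiles
  } else {
    dmat <- matrix(0, nt, nt)
    for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
      dmat[i, j] <- dmat[j, i] <- dtw_align(profiles[[i]],
                                            profiles[[j]])$distance
    }
    medoid <- which.min(rowSums(dmat))
    ref <- profiles[[medoid]]
    warped <- lapply(profiles, function(p) dtw_warp_onto(ref, p))
  }
  mean_prof <- Reduce(`+`, warped) / nt
  sum(vapply(warped, function(w) sum((w - mean_prof)^2), numeric(1))) / nt
}
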