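#' Stage definitions for the contrast analysis
#'
#' The four analysis stages, each the median of a block of 5 trials:
#' `open1_late` (last 5 trials of the first open phase), `tele_early`
#' (first 5 teleoperation trials), `tele_late` (last 5 teleoperation
#' trials) and `open2_early` (first 5 trials of the second open phase).
#' Block medians damp trial-by-trial variability.
#'
#' @param block Trials per stage. Default 5.
#' @return Named list of selectors `list(phase, side, k)`.
#' @export
stage_definitions <- function(block = 5) {
  list(open1_late  = list(phase = "open1", side = "last",  k = block),
       tele_early  = list(phase = "tele",  side = "first", k = block),
       tele_late   = list(phase = "tele",  side = "last",  k = block),
       open2_early = list(phase = "open2", side = "first", k = block))
}

#' Stage value: median of a block of trials
#'
#' @param values Per-trial metric values of one participant, in trial
#'   order, for the stage's phase.
#' @param stage A single stage selector from [stage_definitions()].
#' @return Median of the selected `k` trials. `NA` if all selected values
#'   are `NA`; errors if fewer than `k` trials exist.
#' @export
stage_value <- function(values, stage) {
  if (length(values) < stage$k)
    stop(sprintf("need %d trials, have %d", stage$k, length(values)),
         call. = FALSE)
  sel <- if (stage$side == "first") utils::head(values, stage$k)
         else utils::tail(values, stage$k)
  if (all(is.na(sel))) return(NA_real_)
  stats::median(sel, na.rm = TRUE)
}

contrast_specs <- list(
  learning          = c(minuend = "tele_late",   subtrahend = "tele_early"),
  aftereffect       = c(minuend = "open2_early", subtrahend = "open1_late"),
  final_performance = c(minuend = "tele_late",   subtrahend = "open1_late"))

# Long stage-value table: participant x condition x stage x metric.
stage_table <- function(cohort_metrics, metrics, block = 5) {
  stages <- stage_definitions(block)
  out <- list()
  sp <- split(cohort_metrics,
              cohort_metrics$participant)
  for (p in names(sp)) {
    dp <- sp[[p]][order(sp[[p]]$trial), ]
    for (sname in names(stages)) {
      st <- stages[[sname]]
      dphase <- dp[dp$phase == st$phase, ]
      vals <- unname(vapply(metrics, function(mm) stage_value(dphase[[mm]], st),
                            numeric(1)))
      out[[length(out) + 1]] <- tibble::tibble(
        participant = p, condition = as.character(dp$condition[1]),
        stage = sname, metric = metrics, value = vals)
    }
  }
  do.call(rbind, out)
}

#' Per-participant contrast differences
#'
#' Differences of stage values for one of the three contrasts: learning
#' (tele late - tele early), aftereffect (open-2 early - open-1 late),
#' final performance (tele late - open-1 late). One scalar per
#' participant; `NA` when a stage is unavailable for the metric (e.g.
#' teleoperation-only metrics in contrasts involving open stages).
#'
#' @param stages A stage table (internal long format) or a
#'   [generate_cohort()]-style per-trial table (converted automatically
#'   when it has a `trial` column).
#' @param contrast One of `"learning"`, `"aftereffect"`,
#'   `"final_performance"`.
#' @param metric Metric column name.
#' @param block Trials per stage block (used when converting a per-trial
#'   table). Default 5.
#' @return Tibble with `participant`, `condition`, `diff`.
#' @export
contrast_diffs <- function(stages, contrast = names(contrast_specs),
                           metric, block = 5) {
  contrast <- match.arg(contrast)
  if ("trial" %in% names(stages))
    stages <- stage_table(stages, metrics = metric, block = block)
  spec <- contrast_specs[[contrast]]
  st <- stages[stages$metric == metric, ]
  a <- st[st$stage == spec[["minuend"]], ]
  b <- st[st$stage == spec[["subtrahend"]], ]
  m <- match(a$participant, b$participant)
  tibble::tibble(participant = a$participant, condition = a$condition,
                 diff = a$value - b$value[m])
}

#' Two-sided Wilcoxon signed-rank test
#'
#' Tests whether paired differences are symmetric about zero. Exact zeros
#' are dropped first (classic Wilcoxon). The exact null distribution is
#' used when n <= 25 with no tied absolute differences; otherwise the
#' normal approximation with tie correction (and continuity correction)
#' is used.
#'
#' @param diffs Numeric differences; `NA`s are dropped.
#' @return List with `p` (two-sided), `statistic` (V), `n` (after
#'   dropping zeros), `method`. All-zero input yields `p = NA` (test
#'   undefined).
#' @export
wilcoxon_signed_rank <- function(diffs) {
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 2)
    return(list(p = NA_real_, statistic = NA_real_, n = n,
                method = "undefined"))
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25 && !ties
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0, exact = exact,
                                            correct = TRUE))
  list(p = unname(wt$p.value), statistic = unname(wt$statistic), n = n,
       method = if (exact) "exact" else "normal approximation")
}

# Tie-corrected Kruskal-Wallis H for a vector of values and a grouping.
kw_statistic <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  tab <- tapply(r, groups, function(x) c(sum(x), length(x)))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(tab, function(v) v[1]^2 / v[2], numeric(1))) - 3 * (N + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) return(0)
  H / corr
}

#' Kruskal-Wallis test across feedback conditions
#'
#' Rank-based test that the groups come from the same distribution,
#' with tie correction; the default reference distribution is chi-squared
#' with k - 1 degrees of freedom. `p_method = "permutation"` instead
#' enumerates the full permutation distribution of H (all distinct group
#' assignments), for small samples.
#'
#' @param values Numeric values (`NA` dropped with their group labels).
#' @param groups Group labels, same length.
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param max_perm Safety cap on the number of enumerated assignments for
#'   the permutation method. Default 2e5.
#' @return List with `statistic` (H), `p`, `df`, `method`. Degenerate
#'   all-equal data gives `statistic = 0`, `p = 1`.
#' @export
kruskal_wallis <- function(values, groups, p_method = c("chisq", "permutation"),
                           max_perm = 2e5) {
  p_method <- match.arg(p_method)
  keep <- !is.na(values)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2))
    return(list(statistic = NA_real_, p = NA_real_, df = NA_integer_,
                method = "undefined"))
  if (length(unique(values)) == 1)
    return(list(statistic = 0, p = 1, df = nlevels(groups) - 1L,
                method = "degenerate"))
  kt <- stats::kruskal.test(values, groups)
  H <- unname(kt$statistic)
  if (p_method == "chisq")
    return(list(statistic = H, p = unname(kt$p.value),
                df = unname(kt$parameter), method = "chi-squared"))
  # exhaustive permutation distribution of H over group assignments
  sizes <- as.integer(table(groups))
  n <- length(values)
  total <- factorial(n) / prod(factorial(sizes))
  if (total > max_perm)
    stop("permutation enumeration too large; use p_method = 'chisq'",
         call. = FALSE)
  assigns <- enumerate_assignments(n, sizes)
  Hs <- vapply(assigns, function(g) kw_statistic(values, g), numeric(1))
  p <- mean(Hs >= H - 1e-12)
  list(statistic = H, p = p, df = nlevels(groups) - 1L,
       method = "exact permutation")
}

# All distinct assignments of n items into groups of the given sizes.
enumerate_assignments <- function(n, sizes) {
  res <- list()
  # assign groups 1..k-1 by choice; the last group takes the rest
  recurse2 <- function(remaining, g, labels) {
    if (g == length(sizes)) {
      labels[remaining] <- g
      res[[length(res) + 1L]] <<- labels
      return(invisible())
    }
    for (cc in utils::combn(remaining, sizes[g], simplify = FALSE)) {
      lab2 <- labels
      lab2[cc] <- g
      recurse2(setdiff(remaining, cc), g + 1L, lab2)
    }
  }
  recurse2(seq_len(n), 1L, integer(n))
  res
}

#' Nonparametric bootstrap percentile confidence interval
#'
#' Percentile interval of a statistic (the median by default) over `B`
#' resamples with replacement. Deterministic under a fixed seed. Quantiles
#' use the default continuous method (type 7).
#'
#' @param values Numeric sample (`NA` dropped).
#' @param level Confidence level. Default 0.95.
#' @param B Number of bootstrap resamples. Default 10000.
#' @param seed Integer seed.
#' @param statistic Function of a numeric vector. Default `median`.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, level = 0.95, B = 10000, seed = NULL,
                         statistic = stats::median) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) return(c(NA_real_, NA_real_))
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    stat <- apply(idx, 1, function(i) statistic(values[i]))
    unname(stats::quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' Full contrast analysis
#'
#' Runs the statistical design on a per-trial metric table (e.g. from
#' [generate_cohort()] or [run_pipeline()]): block-median stage values,
#' the three contrasts, per-condition Wilcoxon signed-rank tests with
#' bootstrap confidence intervals on the median difference, and
#' per-contrast Kruskal-Wallis tests across conditions with pairwise
#' comparisons. No multiple-testing correction is applied by default; set
#' `p_adjust = "BH"` for Benjamini-Hochberg adjusted columns.
#'
#' @param cohort_metrics Per-trial table with columns `participant`,
#'   `condition`, `phase`, `trial`, and one column per metric.
#' @param metrics Metric columns to analyze. Default: all columns after
#'   `trial_in_phase` / the standard id columns.
#' @param block Trials per stage block. Default 5.
#' @param bootstrap Compute bootstrap CIs (set `FALSE` to skip, e.g. in
#'   large simulations). Default `TRUE`.
#' @param B Bootstrap resamples. Default 2000.
#' @param conf Confidence level. Default 0.95.
#' @param seed Seed for the bootstrap.
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return An object of class `contrast_tables`: list with `signed_rank`
#'   (metric x contrast x condition: `delta`, `p`, CI), `kruskal_wallis`
#'   (metric x contrast: model `p`, `chi_squared`, pairwise `p` and
#'   `delta`), and the `stages` table.
#' @export
run_full_analysis <- function(cohort_metrics, metrics = NULL, block = 5,
                              bootstrap = TRUE, B = 2000, conf = 0.95,
                              seed = NULL, p_adjust = "none") {
  id_cols <- c("participant", "condition", "phase", "block", "trial",
               "trial_in_phase")
  metrics <- metrics %||% setdiff(names(cohort_metrics), id_cols)
  conds <- levels(factor(cohort_metrics$condition))
  stages <- stage_table(cohort_metrics, metrics, block)

  t1 <- list(); t2 <- list()
  for (mm in metrics) {
    for (ct in names(contrast_specs)) {
      dd <- contrast_diffs(stages, ct, mm)
      for (cond in conds) {
        dcond <- dd$diff[dd$condition == cond]
        avail <- sum(!is.na(dcond))
        if (avail < 2) {
          t1[[length(t1) + 1]] <- tibble::tibble(
            metric = mm, contrast = ct, condition = cond,
            delta = NA_real_, p = NA_real_, ci_lower = NA_real_,
            ci_upper = NA_real_, n = avail)
          next
        }
        wt <- wilcoxon_signed_rank(dcond)
        ci <- if (bootstrap) bootstrap_ci(dcond, conf, B, seed = seed)
              else c(NA_real_, NA_real_)
        t1[[length(t1) + 1]] <- tibble::tibble(
          metric = mm, contrast = ct, condition = cond,
          delta = stats::median(dcond, na.rm = TRUE), p = wt$p,
          ci_lower = ci[1], ci_upper = ci[2], n = avail)
      }
      # Kruskal-Wallis across conditions on the per-participant diffs
      ok <- !is.na(dd$diff)
      if (sum(ok) >= 4 && length(unique(dd$condition[ok])) >= 2) {
        kw <- kruskal_wallis(dd$diff[ok], dd$condition[ok])
        pw <- pairwise_rank_comparisons(dd$diff[ok], dd$condition[ok])
      } else {
        kw <- list(p = NA_real_, statistic = NA_real_)
        pw <- NULL
      }
      t2[[length(t2) + 1]] <- tibble::tibble(
        metric = mm, contrast = ct, p_model = kw$p,
        chi_squared = kw$statistic,
        pair = if (is.null(pw)) NA_character_ else pw$pair,
        p_pair = if (is.null(pw)) NA_real_ else pw$p,
        delta_pair = if (is.null(pw)) NA_real_ else pw$delta)
    }
  }
  t1 <- do.call(rbind, t1)
  t2 <- do.call(rbind, t2)
  if (p_adjust != "none") {
    t1$p_adjusted <- stats::p.adjust(t1$p, method = p_adjust)
    t2$p_model_adjusted <- stats::p.adjust(t2$p_model, method = p_adjust)
  }
  structure(list(signed_rank = t1, kruskal_wallis = t2, stages = stages),
            class = "contrast_tables")
}

# Pairwise two-group rank comparisons: two-group Kruskal-Wallis p and a
# rank-based location difference (difference of the two groups' mean
# ranks in their pooled ranking).
pairwise_rank_comparisons <- function(values, groups) {
  groups <- droplevels(factor(groups))
  levs <- levels(groups)
  out <- list()
  for (i in seq_len(length(levs) - 1)) for (j in (i + 1):length(levs)) {
    sel <- groups %in% c(levs[i], levs[j])
    v <- values[sel]; g <- droplevels(groups[sel])
    kw <- kruskal_wallis(v, g)
    r <- rank(v)
    delta <- mean(r[g == levs[i]]) - mean(r[g == levs[j]])
    out[[length(out) + 1]] <- tibble::tibble(
      pair = paste0(levs[i], "-", levs[j]), p = kw$p, delta = delta)
  }
  do.call(rbind, out)
}

#' @export
print.contrast_tables <- function(x, ...) {
  cat("<contrast_tables>\n")
  cat(sprintf("  signed-rank cells: %d (metrics x contrasts x conditions)\n",
              nrow(x$signed_rank)))
  sig <- sum(x$signed_rank$p < 0.05, na.rm = TRUE)
  cat(sprintf("  signed-rank cells with p < 0.05: %d\n", sig))
  cat(sprintf("  Kruskal-Wallis rows: %d\n", nrow(x$kruskal_wallis)))
  invisible(x)
}

#' Write contrast tables as delimited text
#'
#' @param x A `contrast_tables` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_contrast_tables <- function(x, dir) {
  stopifnot(inherits(x, "contrast_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "signed_rank.csv")
  f2 <- file.path(dir, "kruskal_wallis.csv")
  utils::write.csv(x$signed_rank, f1, row.names = FALSE)
  utils::write.csv(x$kruskal_wallis, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
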