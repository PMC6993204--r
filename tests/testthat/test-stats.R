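test_that("stage values are block medians", {
  st <- stage_definitions()$tele_early
  expect_equal(stage_value(c(1, 2, 3, 4, 100, 7, 7), st), 3)
  expect_equal(stage_value(rep(4.2, 5), st), 4.2)
  expect_error(stage_value(c(1, 2, 3), st), "need 5")
  # last-5 selector
  stl <- stage_definitions()$tele_late
  expect_equal(stage_value(c(9, 9, 1, 2, 3, 4, 100), stl), 3)
  # random 5-sets against a sort-based oracle
  set.seed(40)
  for (k in 1:10) {
    x <- rnorm(5)
    expect_equal(stage_value(x, st), sort(x)[3])
  }
})

test_that("contrast differences subtract the correct stages", {
  co <- generate_cohort(cohort_config(n_per_group = 2, seed = 41))
  # identical stages give zero differences
  co_const <- co
  co_const$completion_time <- 5
  d <- contrast_diffs(co_const, "learning", "completion_time")
  expect_equal(d$diff, rep(0, 6))

  # an injected shift on the late teleoperation trials appears in learning
  co_shift <- co_const
  tele_rows <- which(co_shift$phase == "tele" & co_shift$trial_in_phase > 55)
  co_shift$completion_time[tele_rows] <- 5 + 2.5
  d2 <- contrast_diffs(co_shift, "learning", "completion_time")
  expect_equal(d2$diff, rep(2.5, 6))
  # ... but not in the aftereffect (open stages unchanged)
  d3 <- contrast_diffs(co_shift, "aftereffect", "completion_time")
  expect_equal(d3$diff, rep(0, 6))

  # teleoperation-only metrics are unavailable in open-stage contrasts
  d4 <- contrast_diffs(co, "aftereffect", "exit_point_error")
  expect_true(all(is.na(d4$diff)))
  d5 <- contrast_diffs(co, "final_performance", "exit_point_error")
  expect_true(all(is.na(d5$diff)))
  d6 <- contrast_diffs(co, "learning", "exit_point_error")
  expect_true(all(!is.na(d6$diff)))
})

test_that("signed-rank test matches exhaustive enumeration for n <= 10", {
  # five same-sign differences: p = 2/2^5
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, 5))$p, 0.0625)
  # symmetric pairs of equal magnitude: p = 1
  expect_equal(wilcoxon_signed_rank(c(-2, 2, -1, 1))$p, 1)
  # all zeros: undefined
  expect_true(is.na(wilcoxon_signed_rank(c(0, 0, 0))$p))
  # zeros are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 1, 2, 3, 4, 5))$p, 0.0625)
  # random no-tie fixtures against the sign-flip enumeration oracle
  set.seed(42)
  for (k in 1:25) {
    d <- round(rnorm(sample(4:10, 1)), 3)
    d <- d[d != 0]
    if (any(duplicated(abs(d)))) next
    expect_equal(wilcoxon_signed_rank(d)$p, enum_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis matches the rank formula and its permutation law", {
  kw <- kruskal_wallis(1:9, rep(1:3, each = 3))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  # three identical groups: degenerate, H = 0 and p = 1
  kw0 <- kruskal_wallis(rep(1, 9), rep(1:3, each = 3))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p, 1)
  # chi-squared p agrees with the reference implementation
  set.seed(43)
  x <- rnorm(12); g <- rep(1:3, each = 4)
  expect_equal(kruskal_wallis(x, g)$p, kruskal.test(x, g)$p.value)
  expect_equal(kruskal_wallis(x, g)$statistic,
               unname(kruskal.test(x, g)$statistic))
  # permutation p matches full enumeration on small fixtures
  for (k in 1:3) {
    v <- round(rnorm(8), 3)
    gg <- rep(1:2, each = 4)
    expect_equal(kruskal_wallis(v, gg, p_method = "permutation")$p,
                 enum_kw_p(v, gg), tolerance = 1e-12)
  }
  v9 <- round(rnorm(9), 3)
  g9 <- rep(1:3, each = 3)
  expect_equal(kruskal_wallis(v9, g9, p_method = "permutation")$p,
               enum_kw_p(v9, g9), tolerance = 1e-12)
  # H with ties agrees with the hand formula
  vt <- c(1, 1, 2, 3, 3, 3, 4, 5, 5)
  expect_equal(kruskal_wallis(vt, g9)$statistic, kw_H_oracle(vt, g9))
})

test_that("bootstrap percentile interval behaves and reproduces under seed", {
  expect_equal(bootstrap_ci(rep(3, 10), B = 200, seed = 1), c(3, 3))
  x <- rnorm(10)
  ci1 <- bootstrap_ci(x, B = 500, seed = 7)
  ci2 <- bootstrap_ci(x, B = 500, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], median(x))
  expect_gte(ci1[2], median(x))
  # endpoints monotone in level
  ci80 <- bootstrap_ci(x, level = 0.80, B = 500, seed = 7)
  expect_lte(ci1[1], ci80[1])
  expect_gte(ci1[2], ci80[2])
})

test_that("bootstrap coverage of the median is near nominal", {
  set.seed(44)
  hits <- replicate(1000, {
    x <- rnorm(10)
    ci <- bootstrap_ci(x, B = 1000)
    ci[1] <= 0 && 0 <= ci[2]
  })
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})

test_that("the full analysis emits the declared table schema", {
  co <- generate_cohort(cohort_config(seed = 45))
  res <- run_full_analysis(co, bootstrap = FALSE)
  metrics <- setdiff(names(co), c("participant", "condition", "phase",
                                  "block", "trial", "trial_in_phase"))
  t1 <- res$signed_rank
  expect_setequal(unique(t1$metric), metrics)
  expect_setequal(unique(t1$contrast),
                  c("learning", "aftereffect", "final_performance"))
  expect_setequal(unique(t1$condition), c("NF", "PE", "DF"))
  expect_equal(nrow(t1), length(metrics) * 3 * 3)
  ps <- t1$p[!is.na(t1$p)]
  expect_true(all(ps >= 0 & ps <= 1))
  # teleop-only metrics carry explicit NA outside learning
  sub <- t1[t1$metric == "total_normalized_force" &
              t1$contrast != "learning", ]
  expect_true(all(is.na(sub$delta)))
  # bootstrap CI straddles the median difference when requested
  res2 <- run_full_analysis(co, metrics = "completion_time", B = 200,
                            seed = 2)
  cc <- res2$signed_rank
  ok <- !is.na(cc$delta)
  expect_true(all(cc$ci_lower[ok] <= cc$delta[ok] &
                    cc$delta[ok] <= cc$ci_upper[ok]))
})

test_that("a spiked-in learning effect is detected only where injected", {
  em <- default_effect_model(0)
  em$completion_time$learning <- 0.4
  co <- generate_cohort(cohort_config(effect_model = em, seed = 46))
  res <- run_full_analysis(co, metrics = c("completion_time", "path_length",
                                           "max_force"), bootstrap = FALSE)
  t1 <- res$signed_rank
  spike <- t1[t1$metric == "completion_time" & t1$contrast == "learning", ]
  expect_true(all(spike$p < 0.05))
  others <- t1[t1$metric != "completion_time" & t1$contrast == "learning", ]
  expect_lt(mean(others$p < 0.05, na.rm = TRUE), 0.5)
})
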