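test_that("ideal insertion lies exactly on the needle circle", {
  cfg <- trial_config()
  tr <- generate_ideal_insertion(cfg)
  pf <- fit_plane(tr$position)
  cf <- fit_circle(tr$position, pf)
  expect_lt(max(pf$distances), 1e-9)
  expect_lt(max(abs(cf$s)), 1e-9)
  expect_equal(cf$radius, cfg$needle_radius, tolerance = 1e-9)
  # analytic arc length up to discretization
  pl <- sum(sqrt(rowSums(diff(tr$position)^2)))
  expect_equal(pl, cfg$needle_radius * cfg$arc_span, tolerance = 1e-3)
  # uniform timestamps at the native rate
  expect_equal(diff(tr$t), rep(1 / cfg$sample_rate, length(tr$t) - 1))
  expect_error(trial_config(arc_span = -1), "arc_span")
})

test_that("trial generation is bit-reproducible under a fixed seed", {
  cfg <- trial_config(seed = 77)
  g1 <- generate_trial(cfg)
  g2 <- generate_trial(cfg)
  expect_identical(g1$trial$position, g2$trial$position)
  expect_identical(g1$trial$force, g2$trial$force)
  g3 <- generate_trial(trial_config(seed = 78))
  expect_false(identical(g1$trial$position, g3$trial$position))
})

test_that("generated trials satisfy their own force-threshold structure", {
  gt <- generate_trial(trial_config(seed = 21))
  truth <- schedule_truth_labels(gt$schedule, gt$trial$t)
  driving <- truth %in% c("insertion", "correction", "extraction")
  fmag <- sqrt(rowSums(gt$trial$force^2))
  expect_lt(max(fmag[!driving]), 0.06)
  expect_gt(min(fmag[driving]), 0.06)
  # gripper closed exactly during needle-holding phases
  expect_true(all(gt$trial$gripper[driving] <= 0.5))
  # insertion occupies its scheduled share of the bounded trial
  u <- preprocess_trial(gt$trial)
  seg <- classify_segments(u, gt$geom)
  fr <- relative_durations(seg)
  sched <- gt$schedule
  drv <- sched$label != "outside"
  expect_equal(unname(fr["insertion"]),
               sched$duration[sched$label == "insertion"] /
                 sum(sched$duration[drv]),
               tolerance = 0.02)
})

test_that("schedules violating the subtask ordering are rejected", {
  bad1 <- data.frame(label = c("extraction", "insertion"),
                     duration = c(1, 1))
  expect_error(trial_config(subtask_schedule = bad1), "order")
  bad2 <- data.frame(label = c("insertion", "outside", "extraction"),
                     duration = c(1, 1, 1))
  expect_error(trial_config(subtask_schedule = bad2), "outside")
  bad3 <- data.frame(label = "insertion", duration = 2)
  expect_error(trial_config(subtask_schedule = bad3), "order")
})

test_that("power-law generator honors its degenerate and scaling cases", {
  # beta = gamma = 0: constant speed alpha
  tr0 <- generate_powerlaw_trajectory(0.07, 0, 0)
  u0 <- derivative_chain(tr0)
  sp <- sqrt(rowSums(u0$velocity^2))
  i <- 50:(length(sp) - 50)
  expect_equal(sp[i], rep(0.07, length(i)), tolerance = 1e-3)
  # vanishing torsion or curvature is refused
  flat <- list(f = function(u) cbind(cos(u), sin(u), 0 * u),
               u_range = c(0, 2 * pi))
  expect_error(generate_powerlaw_trajectory(0.05, -1/3, -1/6, flat),
               "torsion")
  straight <- list(f = function(u) cbind(u, 0 * u, 0 * u),
                   u_range = c(0, 1))
  expect_error(generate_powerlaw_trajectory(0.05, -1/3, -1/6, straight),
               "curvature|torsion")
})

test_that("cohort generator produces the full protocol structure", {
  cfg <- cohort_config(seed = 30)
  co <- generate_cohort(cfg)
  expect_equal(length(unique(co$participant)), 30)
  expect_equal(as.vector(table(co$participant)), rep(120L, 30))
  # each participant has exactly one condition
  tab <- table(co$participant, co$condition)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(as.vector(table(co$phase)) / 30, c(40, 60, 20))
  # teleop-only metrics are absent in the open phases
  expect_true(all(is.na(co$exit_point_error[co$phase != "tele"])))
  expect_true(all(!is.na(co$completion_time)))
  # deterministic under seed
  expect_identical(generate_cohort(cfg), co)
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
})

test_that("a null cohort shows no learning and injected effects are recovered", {
  null_cfg <- cohort_config(effect_model = default_effect_model(0), seed = 31)
  co0 <- generate_cohort(null_cfg)
  d0 <- contrast_diffs(co0, "learning", "completion_time")
  expect_lt(abs(median(d0$diff)), 1.0)

  co1 <- generate_cohort(cohort_config(seed = 31))
  d1 <- contrast_diffs(co1, "learning", "completion_time")
  expect_lt(median(d1$diff), -2)          # injected improvement
})

test_that("materialized trials follow their cohort row parameters", {
  co <- generate_cohort(cohort_config(n_per_group = 2, trials_per_block = 5,
                                      blocks = c(open1 = 1, tele = 1,
                                                 open2 = 1), seed = 32))
  i_open <- which(co$phase == "open1")[1]
  i_tele <- which(co$phase == "tele")[1]
  mo <- materialize_trial(co, i_open)
  mt <- materialize_trial(co, i_tele)
  expect_equal(mo$trial$meta$rate, 120)
  expect_equal(mt$trial$meta$rate, 500)
  # bounded duration tracks the row's completion time
  dur <- sum(mo$schedule$duration[mo$schedule$label != "outside"])
  expect_equal(dur, co$completion_time[i_open], tolerance = 1e-6)
})
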