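test_that("binning partitions the trials exactly", {
  trials <- exp1_trials()
  by_unit <- bin_trials(trials, by = c("participant_id", "condition"))
  expect_equal(nrow(by_unit), 22)
  tot <- sum(vapply(by_unit$data, function(d) sum(d$n_trials), numeric(1)))
  expect_equal(tot, nrow(trials))
  expect_true(all(vapply(by_unit$data, function(d)
    all(d$n_trials == 240) && nrow(d) == 7, logical(1))))

  one <- trials[trials$participant_id == "P01" & trials$condition == "happy", ]
  by_face <- bin_trials(one, by = "face_id")
  expect_equal(nrow(by_face), 6)
  expect_true(all(vapply(by_face$data, function(d) sum(d$n_trials), numeric(1))
                  == 280))

  expect_equal(nrow(bin_trials(trials[0, ], by = "condition")), 0)
  expect_error(bin_trials(trials[, 1:3]), "missing column")

  # mixed metadata within a group is flagged
  mixed <- trials[trials$participant_id == "P01", ]
  mixed$duration_ms <- rep(c(8, 200), length.out = nrow(mixed))
  expect_warning(bin_trials(mixed, by = "condition"), "duration_ms")
})

test_that("participant analysis recovers thresholds and detects the gap", {
  cfg <- small_study_config(n_participants = 1, repeats = 40)
  cfg$conditions$happy$threshold_sd <- 0
  cfg$conditions$fear$threshold_sd <- 0
  trials <- make_synthetic_study(cfg, seed = 21)
  rep <- analyze_participant(trials, conditions = c("happy", "fear"),
                             n_sims = 300, seed = 22)
  thr <- setNames(rep$thresholds$threshold, rep$thresholds$condition)
  expect_lt(abs(thr[["happy"]] - 92), 2)
  expect_lt(abs(thr[["fear"]] - 86), 2)
  expect_s3_class(rep$comparison, "pf_lr_test")
  expect_lt(rep$comparison$p_value, 0.05)
  expect_equal(nrow(rep$unfittable), 0)
})

test_that("a null participant is rarely flagged as different", {
  cfg <- small_study_config(n_participants = 1, repeats = 10,
                            happy_mean = 90, fear_mean = 90)
  cfg$conditions$happy$threshold_sd <- 0
  cfg$conditions$fear$threshold_sd <- 0
  rej <- 0
  runs <- 20
  for (i in seq_len(runs)) {
    trials <- make_synthetic_study(cfg, seed = 3000 + i)
    rep <- analyze_participant(trials, conditions = c("happy", "fear"),
                               n_sims = 200, seed = 30)
    if (rep$comparison$p_value < 0.05) rej <- rej + 1
  }
  expect_lte(rej / runs, 0.25)
})

test_that("test-retest sessions are compared within condition", {
  cfg <- small_study_config(n_participants = 1, repeats = 10)
  cfg$sessions <- 2L
  trials <- make_synthetic_study(cfg, seed = 23)
  rep <- analyze_participant(trials, conditions = c("happy", "fear"),
                             n_sims = 200, seed = 24)
  expect_named(rep$retest, c("happy", "fear"))
  # no true session effect: stable functions, typically large p
  expect_gt(rep$retest$happy$p_value, 0.01)
})

test_that("an unfittable face is flagged while others are reported", {
  off <- c(FF1 = -30, FF2 = 6, FF3 = 6, MF1 = 6, MF2 = 6, MF3 = 6)
  obs <- observer_spec(list(happy = pf_params(8, 0.3),
                            fear = pf_params(14, 0.3)),
                       face_offsets = off)
  blocks <- lapply(c("happy", "fear"), function(cond) {
    sched <- generate_schedule(schedule_spec(condition = cond), seed = 25)
    simulate_observer(sched, obs, participant_id = "P01", seed = 26)
  })
  trials <- dplyr::bind_rows(blocks)
  rep <- analyze_participant(trials, conditions = c("happy", "fear"),
                             n_sims = 100, seed = 27, per_face = TRUE)
  ff <- rep$face_fits
  expect_false(ff$fittable[ff$condition == "happy" & ff$face_id == "FF1"])
  expect_true(all(ff$fittable[ff$face_id != "FF1"]))
  expect_true(any(grepl("FF1", rep$unfittable$unit)))

  # with too few per-face trials the face analysis is skipped with a note
  cfg <- small_study_config(n_participants = 1, repeats = 10)
  few <- make_synthetic_study(cfg, seed = 28)
  rep2 <- analyze_participant(few, conditions = c("happy", "fear"),
                              n_sims = 50, seed = 29, per_face = TRUE)
  expect_null(rep2$face_fits)
  expect_true(any(grepl("per-face", rep2$unfittable$unit)))
})

test_that("the group curve averages predicted percent correct", {
  p <- pf_params(8, 0.3)
  f <- fit_pf(exact_binned(p))
  dil <- c(68, 80, 86, 90, 94, 96, 98)

  # single participant: curve equals the fitted function
  gc1 <- group_curve(list(f), dil)
  expect_equal(gc1$mean_pct, 100 * pf_performance(100 - dil, f$params),
               tolerance = 1e-9)
  expect_true(all(diff(gc1$mean_pct) <= 0))
  expect_true(all(gc1$mean_pct >= 50 & gc1$mean_pct <= 100))

  # identical participants: zero spread
  gc3 <- group_curve(list(f, f, f), dil)
  expect_equal(gc3$sem_pct, rep(0, 7))
  expect_equal(gc3$n[1], 3)

  # unfittable fits are excluded
  flat <- fit_pf(binned_data(dil, rep(40, 7), rep(20, 7)))
  expect_equal(group_curve(list(f, flat), dil)$n[1], 1)
  expect_error(group_curve(list(flat)), "fittable")
})

test_that("the paired threshold test reproduces printed effect sizes", {
  expect_equal(round(r_from_t(5.06, 10), 2), 0.85)
  expect_equal(round(r_from_t(5.96, 8), 2), 0.90)

  res <- paired_threshold_test(c(92, 93, 91, 94), c(86, 88, 85, 87))
  expect_equal(res$df, 3)
  expect_equal(res$r, r_from_t(res$t, res$df))
  expect_gt(res$t, 0)

  same <- paired_threshold_test(c(90, 91, 92), c(90, 91, 92))
  expect_equal(same$t, 0)
  expect_equal(same$r, 0)

  expect_error(paired_threshold_test(1:3, 1:4), "paired")
  expect_error(paired_threshold_test(1, 2), "two pairs")
})

test_that("the study pipeline is deterministic and reconciles exclusions", {
  cfg <- small_study_config(n_participants = 3, repeats = 10)
  trials <- make_synthetic_study(cfg, seed = 31)
  r1 <- analyze_study(trials, n_sims = 100, seed = 32)
  r2 <- analyze_study(trials, n_sims = 100, seed = 32)
  expect_identical(r1$group_stats, r2$group_stats)
  expect_identical(
    vapply(r1$participants, function(p) p$comparison$p_value, numeric(1)),
    vapply(r2$participants, function(p) p$comparison$p_value, numeric(1)))

  # exclusion bookkeeping reconciles
  expect_equal(nrow(r1$excluded) +
                 unique(r1$group_stats$n), length(r1$participants))
  expect_s3_class(r1$paired_test$t, NA)
  expect_true(is.numeric(r1$paired_test$r))
  expect_named(r1$group_curves, c("happy", "fear"))
})
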