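test_that("schedules realise the crossed design in complete passes", {
  spec <- schedule_spec(condition = "happy")
  sched <- generate_schedule(spec, seed = 1)
  expect_equal(nrow(sched), 7 * 6 * 40)
  expect_true(all(table(sched$dilution_pct) == 240))
  expect_true(all(table(sched$face_id) == 280))

  # each complete pass holds every (level, face) pair exactly once
  first_pass <- sched[1:42, ]
  expect_equal(nrow(unique(first_pass[, c("dilution_pct", "face_id")])), 42)
  counts <- table(sched$pass, paste(sched$dilution_pct, sched$face_id))
  expect_true(all(counts == 1))

  # determinism under seed, variation without
  expect_identical(sched, generate_schedule(spec, seed = 1))
  expect_false(identical(sched$test_interval,
                         generate_schedule(spec, seed = 2)$test_interval))

  expect_error(schedule_spec(dilution_levels = numeric(0)), "non-empty")
  expect_error(schedule_spec(dilution_levels = c(50, 101)), "\\[0, 100\\]")
})

test_that("the test stimulus lands in the first interval half the time", {
  spec <- schedule_spec(repeats_per_face = 240) # 7 * 6 * 240 = 10080 slots
  sched <- generate_schedule(spec, seed = 3)
  n <- nrow(sched)
  expect_gte(n, 10000)
  prop <- mean(sched$test_interval == 1)
  expect_lt(abs(prop - 0.5), 3 * 0.5 / sqrt(n))
  expect_true(all(sched$test_interval %in% c(1L, 2L)))
})

test_that("simulated responses follow the generating performance function", {
  obs <- observer_spec(list(happy = pf_params(8, 0.3)))

  # at 100% dilution the test equals the comparison: chance performance
  chance <- schedule_spec(dilution_levels = 100, face_ids = "FF1",
                          repeats_per_face = 10000, condition = "happy")
  tr <- simulate_observer(generate_schedule(chance, seed = 4), obs, seed = 5)
  expect_lt(abs(mean(tr$correct) - 0.5), 3 * 0.5 / sqrt(10000))

  # far above threshold (lapse-free) every trial is correct
  easy <- schedule_spec(dilution_levels = 2, face_ids = "FF1",
                        repeats_per_face = 2000, condition = "happy")
  tr <- simulate_observer(generate_schedule(easy, seed = 6), obs, seed = 7)
  expect_true(all(tr$correct))

  # intermediate level: empirical proportion inside the 99% binomial band
  mid <- schedule_spec(dilution_levels = 92, face_ids = "FF1",
                       repeats_per_face = 10000, condition = "happy")
  tr <- simulate_observer(generate_schedule(mid, seed = 8), obs, seed = 9)
  psi <- pf_performance(100 - 92, pf_params(8, 0.3)) # 0.75
  band <- qnorm(0.995) * sqrt(psi * (1 - psi) / 10000)
  expect_lt(abs(mean(tr$correct) - psi), band)

  # the reported interval encodes correctness
  expect_identical(tr$correct, tr$response_interval == tr$test_interval)
})

test_that("expected performance is monotone nonincreasing in dilution", {
  obs <- observer_spec(list(happy = pf_params(8, 0.3)))
  spec <- schedule_spec(repeats_per_face = 200) # 1200 per level
  tr <- simulate_observer(generate_schedule(spec, seed = 10), obs, seed = 11)
  props <- tapply(tr$correct, tr$dilution_pct, mean)
  # allow small sampling wiggles but no real inversion
  expect_true(all(diff(props[order(as.numeric(names(props)))]) <= 0.04))
})

test_that("per-face offsets shift thresholds in the right direction", {
  off <- c(FF1 = -6, FF2 = 6) # FF1 harder (lower dilution threshold)
  obs <- observer_spec(list(happy = pf_params(8, 0.3)), face_offsets = off)
  expect_equal(sum(obs$face_offsets), 0)
  spec <- schedule_spec(dilution_levels = 92, face_ids = c("FF1", "FF2"),
                        repeats_per_face = 4000, condition = "happy")
  tr <- simulate_observer(generate_schedule(spec, seed = 12), obs, seed = 13)
  p1 <- mean(tr$correct[tr$face_id == "FF1"])
  p2 <- mean(tr$correct[tr$face_id == "FF2"])
  expect_lt(p1 + 0.05, p2)
  expect_error(simulate_observer(
    generate_schedule(schedule_spec(condition = "fear"), seed = 1), obs),
    "fear")
})

test_that("study generation is reproducible and streams are per participant", {
  cfg <- small_study_config(n_participants = 3, repeats = 2)
  t1 <- make_synthetic_study(cfg, seed = 5)
  t2 <- make_synthetic_study(cfg, seed = 5)
  expect_identical(t1, t2)

  # adding a participant must not perturb existing participants' trials
  cfg4 <- cfg
  cfg4$participants <- sprintf("P%02d", 1:4)
  t4 <- make_synthetic_study(cfg4, seed = 5)
  strip <- function(x) {
    attr(x, "truth") <- NULL
    as.data.frame(x)
  }
  expect_identical(strip(t1),
                   strip(t4[t4$participant_id %in% cfg$participants, ]))
})

test_that("the exp1 preset matches its design counts", {
  trials <- exp1_trials()
  expect_equal(length(unique(trials$participant_id)), 11)
  expect_setequal(unique(trials$condition), c("happy", "fear"))
  counts <- dplyr::count(trials, participant_id, condition, dilution_pct)
  expect_true(all(counts$n == 240))            # 40 repeats x 6 faces
  expect_equal(nrow(counts), 11 * 2 * 7)       # 7 levels per unit
  truth <- attr(trials, "truth")
  expect_equal(nrow(truth), 22)
  expect_error(make_synthetic_study(list(participants = "P1")), "config")
})
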