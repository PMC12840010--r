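test_that("trajectory simulation handles empty and invalid durations", {
  geom <- test_geometry()
  expect_equal(nrow(simulate_trajectory(geom, 0)), 0)
  expect_error(simulate_trajectory(geom, -5), "nonnegative")
})

test_that("trajectories are deterministic under a seed and stay in the arena", {
  geom <- test_geometry()
  a <- simulate_trajectory(geom, 30, seed = 9)
  b <- simulate_trajectory(geom, 30, seed = 9)
  expect_identical(a, b)
  c <- simulate_trajectory(geom, 30, seed = 10)
  expect_false(identical(a, c))
  expect_true(all(in_arena(cbind(a$body_x, a$body_y), geom, tol = 1e-6)))
  expect_true(all(in_arena(cbind(a$head_x, a$head_y), geom, tol = 1e-6)))
})

test_that("trajectories contain both resting and running bouts", {
  geom <- test_geometry()
  trk <- simulate_trajectory(geom, 300, seed = 11)
  sp <- compute_speed(trk)
  expect_gt(mean(sp$speed < 2), 0.01)
  expect_gt(mean(sp$speed > 2), 0.5)
})

test_that("a 40-minute trajectory covers over 90% of arena bins", {
  geom <- test_geometry()
  trk <- simulate_trajectory(geom, 2400, seed = 12)
  occ <- bin_occupancy(trk, geom)
  inb <- occ[occ$in_arena, ]
  expect_gte(mean(inb$seconds >= 0.5), 0.9)
})

test_that("trial schedules balance contexts and respect timing invariants", {
  geom <- test_geometry()
  trk <- simulate_trajectory(geom, 1200, seed = 13)
  for (n in c(7, 24)) {
    trl <- simulate_trial_sequence(geom, trk, n, seed = 14)
    counts <- table(factor(trl$context, levels = geom$contexts))
    expect_lte(abs(counts[1] - counts[2]), 1)
    expect_true(all(trl$trigger_frame >= trl$start_frame + 10 * 20))
    expect_true(all(trl$end_frame >= trl$trigger_frame))
    # disjoint ordered trials
    expect_true(all(diff(trl$start_frame) > 0))
    expect_true(all(utils::head(trl$end_frame, -1) < trl$start_frame[-1]))
  }
})

test_that("the perfect agent is always correct; the random agent is at 1/8", {
  geom <- test_geometry()
  trk <- simulate_trajectory(geom, 1500, seed = 15)
  perfect <- simulate_trial_sequence(geom, trk, 20, seed = 16,
                                     policy = "perfect")
  expect_true(all(perfect$outcome == "correct"))
  # pool random-agent outcomes across schedules: binomial CI around 1/8
  hits <- trials <- 0
  for (s in 1:6) {
    rnd <- simulate_trial_sequence(geom, trk, 45, seed = 20 + s,
                                   policy = "random", p_timeout = 0)
    hits <- hits + sum(rnd$outcome == "correct")
    trials <- trials + nrow(rnd)
  }
  ci <- stats::binom.test(hits, trials, p = 1 / 8)$conf.int
  expect_true(ci[1] <= 1 / 8 && 1 / 8 <= ci[2])
})

test_that("timeout trials last 60 s after the tone", {
  geom <- test_geometry()
  trk <- simulate_trajectory(geom, 2000, seed = 17)
  trl <- simulate_trial_sequence(geom, trk, 15, seed = 18, policy = "random",
                                 p_timeout = 0.5)
  to <- trl[trl$outcome == "timeout" & trl$end_frame < max(trl$end_frame), ]
  expect_gt(nrow(to), 0)
  expect_true(all(to$end_frame - to$trigger_frame == 60 * 20))
})

test_that("a truncated schedule warns", {
  geom <- test_geometry()
  trk <- simulate_trajectory(geom, 120, seed = 19)
  expect_warning(simulate_trial_sequence(geom, trk, 50, seed = 20),
                 "exhausted")
})

test_that("event trains are silent when all rates are zero", {
  geom <- test_geometry()
  truth <- make_ground_truth(geom, n_place = 1, baseline = 1e-12,
                             amp = 1e-12, seed = 21)
  truth$fields[[1]]$amp <- 0
  truth$baseline <- 0
  ses <- simulate_session(truth, geom, duration = 120, n_trials = 3, seed = 22)
  expect_equal(nrow(ses$events), 0)
})

test_that("baseline-only cells fire at the planted Poisson rate", {
  geom <- test_geometry()
  truth <- make_ground_truth(geom, n_background = 6, bg_rate = 6, seed = 23)
  ses <- simulate_session(truth, geom, duration = 2400, n_trials = 60,
                          seed = 24)
  counts <- table(factor(ses$events$neuron, levels = truth$neuron))
  # 6 events/min for 40 min: within 3 Poisson standard errors of 240
  expect_true(all(abs(counts - 240) <= 3 * sqrt(240)))
})

test_that("a silenced context gain removes in-field firing in that context", {
  geom <- test_geometry()
  truth <- make_ground_truth(geom, n_place = 1, remapping = "rate",
                             gain = c(1, 0), baseline = 0.05, seed = 25)
  ses <- simulate_session(truth, geom, duration = 2400, n_trials = 70,
                          seed = 26)
  ctr <- truth$fields[[1]]
  d2 <- (ses$tracking$head_x - ctr$center_x)^2 +
    (ses$tracking$head_y - ctr$center_y)^2
  in_field <- d2 <= (2 * ctr$width)^2
  ctx <- remapflow:::frame_context_index(ses$trials, geom$contexts,
                                         ses$n_frames)
  ev <- rep(FALSE, ses$n_frames)
  ev[ses$events$frame + 1] <- TRUE
  rate_B <- sum(ev & in_field & ctx == 2, na.rm = TRUE) /
    (sum(in_field & !is.na(ctx) & ctx == 2) / 20 / 60)
  rate_A <- sum(ev & in_field & ctx == 1, na.rm = TRUE) /
    (sum(in_field & !is.na(ctx) & ctx == 1) / 20 / 60)
  expect_gt(rate_A, 10)
  expect_lt(rate_B, 1) # at baseline
})

test_that("event trains are reproducible under a seed", {
  ses1 <- small_session()
  truth <- small_truth()
  geom <- test_geometry()
  ev2 <- simulate_event_trains(truth, geom, ses1$tracking, ses1$trials,
                               seed = remapflow:::child_seed(105, 3))
  expect_identical(ses1$events, ev2)
})

test_that("datasets round-trip losslessly through write/read", {
  ses <- small_session()
  dir <- withr::local_tempdir()
  write_dataset(ses, dir)
  back <- read_dataset(dir)
  expect_equal(back$tracking$head_x, ses$tracking$head_x)
  expect_equal(back$trials$trigger_frame, ses$trials$trigger_frame)
  expect_equal(back$trials$context, ses$trials$context)
  expect_identical(back$events, ses$events)
  expect_equal(back$geometry$walls, ses$geometry$walls)
  expect_equal(back$frame_rate, ses$frame_rate)
  # planted truth joins by neuron id for recovery tests
  expect_setequal(back$truth$neuron, ses$truth$neuron)
  ord <- match(ses$truth$neuron, back$truth$neuron)
  expect_equal(back$truth$cell_class[ord], ses$truth$cell_class)
  expect_equal(back$truth$fields[[ord[1]]]$center_x,
               ses$truth$fields[[1]]$center_x)
})

test_that("an empty neuron set writes a valid dataset with no event files", {
  geom <- test_geometry()
  ses <- small_session()
  empty <- remapflow:::new_session(geom, ses$tracking, ses$trials,
                                   ses$events[0, ], NULL)
  dir <- withr::local_tempdir()
  write_dataset(empty, dir)
  expect_length(list.files(file.path(dir, "events")), 0)
  back <- read_dataset(dir)
  expect_equal(nrow(back$events), 0)
})

test_that("calcium traces convolve events and QC flags drift as unstable", {
  ev <- tibble::tibble(neuron = 1L, frame = c(100L, 500L, 3000L))
  n <- 20 * 60 * 8 # 8 minutes
  stable <- simulate_calcium_traces(ev, n, seed = 30, stability = "stable")
  unstable <- simulate_calcium_traces(ev, n, seed = 30,
                                      stability = "unstable")
  expect_equal(label_trace_stability(stable$dff)$stability, "stable")
  expect_equal(label_trace_stability(unstable$dff)$stability, "unstable")
  # pure-noise trace: every 1-min valley stays below 0.1 dF/F0
  noise <- simulate_calcium_traces(ev[0, ], n, seed = 31)
  expect_equal(label_trace_stability(noise$dff)$stability, "stable")
})

test_that("each planted event yields exactly one deconvolved peak", {
  # spaced events (adjacent-frame events merge into one deconvolved plateau)
  withr::local_seed(35)
  ev <- tibble::tibble(neuron = 1L, frame = sort(sample(0:1199, 40)) * 2L)
  tr <- simulate_calcium_traces(ev, 2400, seed = 32)
  det <- detect_events(tr[, c("neuron", "frame", "deconv")],
                       min_prominence = 0.5)
  expect_identical(det$frame, ev$frame)
})
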