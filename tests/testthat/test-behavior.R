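test_that("trial outcomes and error taxonomy follow the port geometry", {
  geom <- test_geometry() # A rewards W (wall 4), B rewards E (wall 0)
  trials <- tibble::tibble(
    trial = 1:6,
    context = c("A", "A", "A", "A", "B", "A"),
    cued = FALSE,
    outcome = c("correct", "incorrect", "incorrect", "incorrect",
                "incorrect", "timeout"),
    visited_port = c(4L, 0L, 3L, 6L, 3L, NA)
  )
  cls <- classify_trials(trials, geom)
  expect_equal(cls$outcome_check,
               c("correct", "incorrect", "incorrect", "incorrect",
                 "incorrect", "timeout"))
  # visited port rewarded in the other context: context error
  expect_equal(cls$error_type[2], "context")
  # adjacent to the correct port: spatial precision error
  expect_equal(cls$error_type[3], "spatial_precision")
  # any other port: non-specific
  expect_equal(cls$error_type[4], "non_specific")
  # context B, visited 3: not E(0), not adjacent to 0 -> non-specific
  expect_equal(cls$error_type[5], "non_specific")
  expect_true(is.na(cls$error_type[6]))
  expect_error(classify_trials(dplyr::mutate(trials[2, ],
                                             visited_port = NA_integer_),
                               geom),
               "malformed")
})

test_that("error precedence resolves ports satisfying two definitions", {
  # geometry where the other context's reward is adjacent to the own reward
  geom <- arena_geometry(reward_walls = c(A = 4L, B = 5L))
  trials <- tibble::tibble(trial = 1, context = "A", cued = FALSE,
                           outcome = "incorrect", visited_port = 5L)
  cls <- classify_trials(trials, geom)
  expect_equal(cls$error_type, "context") # context beats spatial precision
})

test_that("generalization trials cannot produce context errors", {
  geom <- arena_geometry(paradigm = "generalization")
  trials <- tibble::tibble(trial = 1:8, context = rep(c("C", "D"), 4),
                           cued = FALSE, outcome = "incorrect",
                           visited_port = rep(0:3, 2))
  cls <- classify_trials(trials, geom)
  expect_false(any(cls$error_type == "context", na.rm = TRUE))
})

test_that("error-type partition is exhaustive on simulated schedules", {
  geom <- test_geometry()
  trk <- simulate_trajectory(geom, 1500, seed = 80)
  trl <- simulate_trial_sequence(geom, trk, 40, seed = 81, policy = "random",
                                 p_timeout = 0.1)
  cls <- classify_trials(trl, geom)
  expect_identical(cls$outcome_check, cls$outcome)
  bad <- cls$outcome_check == "incorrect"
  expect_true(all(!is.na(cls$error_type[bad])))
  expect_true(all(is.na(cls$error_type[!bad])))
})

test_that("chi-squared composition matches the brute-force formula", {
  prop <- c(context = 0.5, spatial_precision = 0.25, non_specific = 0.25)
  expect_equal(error_composition(c(context = 10, spatial_precision = 5,
                                   non_specific = 5), prop)$statistic, 0)
  hand <- error_composition(c(context = 16, spatial_precision = 2,
                              non_specific = 2), prop)
  expect_equal(hand$statistic, 3.6 + 1.8 + 1.8)
  expect_equal(hand$df, 2)
  # random small tables against sum((O-E)^2/E) and stats::chisq.test
  set.seed(82)
  for (i in 1:15) {
    k <- sample(3:5, 1)
    obs <- stats::setNames(rpois(k, 8) + 1, paste0("c", 1:k))
    p <- stats::setNames(runif(k, 0.5, 2), names(obs))
    res <- error_composition(obs, p)
    p_norm <- p / sum(p)
    expect_equal(res$statistic, sum((obs - sum(obs) * p_norm)^2 /
                                      (sum(obs) * p_norm)))
    ref <- suppressWarnings(stats::chisq.test(obs, p = p_norm))
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p_value, ref$p.value)
  }
  # Bonferroni correction multiplies and caps
  one <- error_composition(c(a = 30, b = 1), c(a = 0.5, b = 0.5),
                           n_comparisons = 4)
  expect_equal(one$p_adjusted, min(1, one$p_value * 4))
})

test_that("zero-expected categories are pooled with a warning", {
  expect_warning(
    res <- error_composition(c(a = 10, b = 5, c = 2),
                             c(a = 0.7, b = 0.3, c = 0)),
    "pooling")
  expect_equal(res$df, 1)
})

test_that("performance summary finds the criterion day by direct scan", {
  mk_day <- function(day, frac, n = 20) {
    tibble::tibble(day = day, cued = FALSE,
                   outcome_check = rep(c("correct", "incorrect"),
                                       c(round(n * frac),
                                         n - round(n * frac))),
                   error_type = NA_character_)
  }
  ramp <- dplyr::bind_rows(lapply(1:6, function(d) {
    mk_day(d, 0.4 + 0.1 * (d - 1))
  }))
  res <- performance_summary(ramp)
  scan <- res$by_day$day[which(res$by_day$fraction_correct >= 0.7)[1]]
  expect_equal(res$days_to_criterion, scan)
  expect_equal(res$days_to_criterion, 4)
  # all correct on day one
  expect_equal(performance_summary(mk_day(1, 1))$days_to_criterion, 1)
  # constant sub-criterion performance: never reached
  flat <- dplyr::bind_rows(lapply(1:4, function(d) mk_day(d, 0.5)))
  expect_true(is.na(performance_summary(flat)$days_to_criterion))
})
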