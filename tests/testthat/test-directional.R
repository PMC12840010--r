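test_that("relative running direction handles the canonical geometries", {
  cfg <- remap_config(speed_smooth_ms = 1) # no smoothing: pure geometry
  mk <- function(xs, ys) tibble::tibble(frame = seq_along(xs) - 1L,
                                        head_x = xs, head_y = ys)
  # at (0,-10) moving +y toward reference (0,0): H = 0
  toward <- relative_running_direction(mk(c(0, 0, 0), c(-10, -9, -8)),
                                       c(0, 0), cfg)
  expect_equal(toward$H, c(0, 0))
  # moving -y, away: boundary case maps to -pi
  away <- relative_running_direction(mk(c(0, 0, 0), c(-10, -11, -12)),
                                     c(0, 0), cfg)
  expect_equal(away$H, c(-pi, -pi))
  # moving +x at (0,-10): heading 0, bearing pi/2, H = -pi/2
  cross <- relative_running_direction(mk(c(0, 1, 2), c(-10, -10, -10)),
                                      c(0, 0), cfg)
  expect_equal(cross$H[1], -pi / 2) # at (0,-10); the bearing turns after that
})

test_that("H agrees with a vector cross/dot oracle on random walks", {
  cfg <- remap_config(speed_smooth_ms = 1)
  set.seed(60)
  for (i in 1:5) {
    n <- 40
    xs <- cumsum(stats::rnorm(n)); ys <- cumsum(stats::rnorm(n))
    ref <- stats::runif(2, -10, 10)
    res <- relative_running_direction(
      tibble::tibble(frame = 0:(n - 1), head_x = xs, head_y = ys), ref, cfg)
    for (k in seq_len(nrow(res))) {
      j <- res$frame[k] + 1L
      v <- c(xs[j + 1] - xs[j], ys[j + 1] - ys[j])   # heading vector
      u <- c(ref[1] - xs[j], ref[2] - ys[j])         # bearing vector
      oracle <- atan2(v[2] * u[1] - v[1] * u[2], sum(v * u))
      expect_equal(remapflow:::wrap_angle(res$H[k] - oracle), 0,
                   tolerance = 1e-9)
    }
  }
})

test_that("Rayleigh vectors behave at the symmetry limits", {
  theta <- remapflow:::dir_bin_centers(8)
  uniform <- rep(2, 8)
  expect_equal(remapflow:::rayleigh_vector(uniform, theta)[["length"]], 0)
  single <- c(0, 0, 0, 5, 0, 0, 0, 0)
  rv <- remapflow:::rayleigh_vector(single, theta)
  expect_equal(rv[["length"]], 1)
  expect_equal(rv[["angle"]], theta[4])
  # length invariant, angle equivariant under rotation by one bin
  set.seed(61)
  curve <- runif(8)
  r0 <- remapflow:::rayleigh_vector(curve, theta)
  r1 <- remapflow:::rayleigh_vector(c(curve[8], curve[1:7]), theta)
  expect_equal(r1[["length"]], r0[["length"]])
  expect_equal(remapflow:::wrap_angle(r1[["angle"]] - r0[["angle"]] - pi / 4),
               0)
})

test_that("planted von Mises tuning is recovered within one angular bin", {
  ses <- small_session() # neuron 3 is a pure directional cell
  truth <- small_truth()
  tun <- directional_tuning(ses, neuron = 3, context = "A")
  expect_equal(nrow(tun), 8)
  diffs <- abs(remapflow:::wrap_angle(tun$angle[1] - truth$dir_mu[3]))
  expect_lt(diffs, pi / 4)
})

test_that("reconstruction is exact for separable degenerate cases", {
  # constant spatial map: r'(H) is constant regardless of occupancy bias
  P <- matrix(rpois(40, 5) + 1, 5, 8)
  smap <- rep(3, 5)
  curve <- rep(2, 8)
  rec <- remapflow:::reconstruction_errors(smap, curve, P)
  # both observations flat: errors undefined, cell excluded
  expect_true(is.na(rec[["err_place"]]))
  expect_true(is.na(rec[["index"]]))
  # flat map with tuned curve: place assumption cannot reproduce tuning
  curve2 <- c(8, 4, 1, 0.5, 0.2, 0.5, 1, 4)
  rec2 <- remapflow:::reconstruction_errors(smap, curve2, P)
  expect_gt(rec2[["err_place"]], 0)
})

test_that("directional analysis separates tuned from place-driven cells", {
  ses <- small_session()
  dres <- directional_analysis(ses, n_shuffle = 100, seed = 62)
  expect_setequal(unique(dres$context), c("A", "B"))
  d3 <- dres[dres$neuron == 3, ] # planted directional cell
  expect_gt(max(d3$L, na.rm = TRUE), 0.3)
  # tuned cell carries a higher direction/place index than background cells
  expect_gt(max(d3$index, na.rm = TRUE),
            max(dres$index[dres$neuron %in% 5:6], na.rm = TRUE))
  expect_true(all(dres$L >= 0 & dres$L <= 1, na.rm = TRUE))
  dcls <- classify_directional_cells(
    dres, tibble::tibble(neuron = 1:6,
                         is_place_cell = c(TRUE, TRUE, FALSE, TRUE,
                                           FALSE, FALSE)))
  expect_false(any(dcls$is_DC[dcls$neuron %in% 5:6]))
  # conjunctive requires both flags
  expect_equal(dcls$is_conjunctive, dcls$is_DC & dcls$is_place_cell)
})

test_that("DC classification rules and selectivity labels", {
  mk <- function(pass1, pass2, a1 = 0.1, a2 = 0.2) {
    tibble::tibble(neuron = 1, context = c("A", "B"), n_events = c(30, 30),
                   angle = c(a1, a2), pass = c(pass1, pass2))
  }
  both <- classify_directional_cells(mk(TRUE, TRUE))
  expect_true(both$is_DC)
  expect_equal(both$context_selectivity, "both")
  expect_equal(both$tuning_difference, 0.1)
  one <- classify_directional_cells(mk(TRUE, FALSE))
  expect_equal(one$context_selectivity, "context-1-only")
  none <- classify_directional_cells(mk(FALSE, FALSE))
  expect_false(none$is_DC)
  # event floor: 10 events over the session
  few <- classify_directional_cells(mk(TRUE, TRUE),
                                    total_events = c(`1` = 9))
  expect_false(few$is_DC)
})

test_that("a planted both-context cell keeps its angle across contexts", {
  geom <- test_geometry()
  truth <- make_ground_truth(geom, n_directional = 3, dir_context = "both",
                             seed = 63)
  ses <- simulate_session(truth, geom, duration = 1800, n_trials = 50,
                          seed = 64, policy = "biased")
  dres <- directional_analysis(ses, n_shuffle = 100, seed = 65)
  dcls <- classify_directional_cells(dres)
  # a 30-minute session has the power to detect the planted tuning
  expect_gt(mean(dcls$is_DC), 0.5)
  diffs <- dcls$tuning_difference[!is.na(dcls$tuning_difference)]
  expect_gt(length(diffs), 0)
  expect_true(all(diffs < pi / 4))
})

test_that("landmark composition counts walls and applies the exclusion", {
  geom <- test_geometry() # wall 0 is light cue (A) and reward (B): excluded
  classified <- tibble::tibble(
    neuron = 1:4, is_DC = TRUE,
    context_selectivity = "both", tuning_difference = 0,
    tuned_angle = c(0, pi, pi / 2, -pi / 2), # walls 0, 4, 2, 6
    is_place_cell = TRUE, is_conjunctive = TRUE
  )
  lt <- landmark_tuning_summary(classified, geom)
  expect_equal(lt$cells$wall, c(0L, 4L, 2L, 6L))
  # wall 0 excluded; wall 4 reward; wall 2 light cue; wall 6 other
  expect_equal(lt$composition$n, c(1, 1, 1))
  expect_equal(sum(lt$composition$chance), 1)
  expect_equal(lt$composition$chance,
               c(1 / 7, 3 / 7, 3 / 7)) # 7 walls after exclusion
  # all-other geometry: every tuned cell lands in "other"
  geo2 <- arena_geometry(lightcue_walls = list(A = integer(), B = integer()),
                         reward_walls = c(A = 4L, B = 0L))
  geo2$walls$reward_1 <- FALSE
  geo2$walls$reward_2 <- FALSE
  lt2 <- landmark_tuning_summary(classified, geo2)
  expect_equal(lt2$composition$n, c(0, 0, 4))
})

test_that("reward-tuned conjunctive cells report closest-field distance", {
  geom <- test_geometry()
  classified <- tibble::tibble(
    neuron = 1, is_DC = TRUE, context_selectivity = "both",
    tuning_difference = 0, tuned_angle = pi, # wall 4 = reward A
    is_place_cell = TRUE, is_conjunctive = TRUE
  )
  ports <- reward_ports(geom)
  fields <- assign_reward_fields(
    tibble::tibble(neuron = c(1, 1), field = 1:2,
                   center_x = c(ports$x[1] + 3, 0),
                   center_y = c(ports$y[1], 0)), geom)
  lt <- landmark_tuning_summary(classified, geom, fields)
  expect_equal(nrow(lt$reward_tuned_distance), 1)
  expect_equal(lt$reward_tuned_distance$closest_field_distance, 3)
})
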