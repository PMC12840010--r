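test_that("rate overlap identities and symmetry", {
  expect_equal(rate_overlap(2, 2), 1)
  expect_equal(rate_overlap(3, 1), 0.5)
  expect_equal(rate_overlap(5, 0), 0)
  expect_true(is.na(rate_overlap(0, 0)))
  set.seed(50)
  a <- runif(50, 0, 10); b <- runif(50, 0, 10)
  expect_equal(rate_overlap(a, b), rate_overlap(b, a))
  expect_true(all(rate_overlap(a, b) >= 0 & rate_overlap(a, b) <= 1))
  expect_true(all((rate_overlap(a, a) == 1) == (a + a > 0)))
})

test_that("flat maps yield zero fields", {
  geom <- test_geometry()
  truth <- make_ground_truth(geom, n_background = 1, bg_rate = 3, seed = 51)
  ses <- simulate_session(truth, geom, duration = 600, n_trials = 15,
                          seed = 52)
  # a homogeneous cell has no 1 event/min prominent peak structure of a field
  flds <- segment_place_fields(ses, neurons = 999L)
  expect_equal(nrow(flds), 0)
})

test_that("single and double planted fields are recovered with k and centres", {
  geom <- test_geometry()
  truth <- dplyr::bind_rows(
    make_ground_truth(geom, n_place = 1, n_fields = 1, seed = 53),
    make_ground_truth(geom, n_place = 1, n_fields = 2, seed = 54)
  )
  truth$neuron <- 1:2
  ses <- simulate_session(truth, geom, duration = 2400, n_trials = 70,
                          seed = 55, policy = "biased")
  flds <- segment_place_fields(ses)
  expect_equal(sum(flds$neuron == 1), 1)
  expect_equal(sum(flds$neuron == 2), 2)
  # centres within 3 cm; fields of one neuron pixel-disjoint
  for (id in 1:2) {
    tf <- truth$fields[[id]]
    ef <- flds[flds$neuron == id, ]
    errs <- vapply(seq_len(nrow(ef)), function(j) {
      min(sqrt((tf$center_x - ef$center_x[j])^2 +
                 (tf$center_y - ef$center_y[j])^2))
    }, numeric(1))
    expect_true(all(errs <= 3))
    pix <- unlist(ef$pixels)
    expect_equal(length(pix), length(unique(pix)))
  }
  # member pixels all reach 20% of the field peak; peak >= mean
  for (j in seq_len(nrow(flds))) {
    expect_gte(flds$peak_rate[j], flds$mean_rate[j])
    expect_gt(flds$size[j], 0)
  }
  # overlap of a stable cell is high
  maps <- context_rate_maps(ses)
  fo <- field_rate_overlap(flds, maps)
  expect_true(all(fo$overlap > 0.6))
})

test_that("field overrides drop and merge fields reproducibly", {
  fields <- tibble::tibble(
    neuron = c(1, 1, 2), field = c(1, 2, 1),
    center_x = c(0, 10, -5), center_y = c(0, 0, 5),
    size = c(40, 60, 80), peak_rate = c(5, 8, 3), mean_rate = c(2, 3, 1),
    n_pixels = c(10, 15, 20), n_events = c(20, 30, 10),
    pixels = list(1:10, 11:25, 30:49)
  )
  dropped <- apply_field_overrides(fields,
                                   list(drop = list(list(neuron = 2,
                                                         field = 1))))
  expect_equal(nrow(dropped), 2)
  merged <- apply_field_overrides(fields,
                                  list(merge = list(list(neuron = 1,
                                                         fields = c(1, 2)))))
  expect_equal(sum(merged$neuron == 1), 1)
  expect_equal(merged$n_pixels[merged$neuron == 1], 25)
  expect_equal(merged$peak_rate[merged$neuron == 1], 8)
})

test_that("reward-field assignment uses the closer port and 5 cm bins", {
  geom <- test_geometry() # rewards at W and E ports (apothem ~18.48 cm)
  ports <- reward_ports(geom)
  fields <- tibble::tibble(
    center_x = c(ports$x[1], ports$x[1] + 12, 0, ports$x[1] + 14),
    center_y = c(ports$y[1], ports$y[1], 18, 9)
  )
  rf <- assign_reward_fields(fields, geom)
  expect_equal(rf$reward_distance[1], 0)
  expect_true(rf$is_reward_field[1])
  expect_equal(rf$distance_class[2], "10-15")
  expect_false(rf$is_reward_field[2])
  # min rule: closer of the two ports decides
  d_manual <- pmin(sqrt((fields$center_x - ports$x[1])^2 +
                          (fields$center_y - ports$y[1])^2),
                   sqrt((fields$center_x - ports$x[2])^2 +
                          (fields$center_y - ports$y[2])^2))
  expect_equal(rf$reward_distance, d_manual)
})

test_that("firing preference signs follow the reward index", {
  # synthetic maps: constant rates per context over a tiny grid
  mk_maps <- function(r1, r2) {
    dplyr::bind_rows(
      tibble::tibble(neuron = 1, context = "A", x = 1:4, y = 1,
                     rate = r1, occupancy = 1, valid = TRUE),
      tibble::tibble(neuron = 1, context = "B", x = 1:4, y = 1,
                     rate = r2, occupancy = 1, valid = TRUE)
    )
  }
  base <- tibble::tibble(neuron = 1, field = 1, center_x = 0, center_y = 0,
                         pixels = list(1:4), is_reward_field = TRUE,
                         reward_index = 1L)
  p1 <- classify_field_preference(base, mk_maps(4, 1))
  expect_equal(p1$preference, 0.6)
  expect_equal(p1$category, "match")
  base$reward_index <- 2L
  p2 <- classify_field_preference(base, mk_maps(4, 1))
  expect_equal(p2$preference, -0.6)
  expect_equal(p2$category, "mismatch")
  p3 <- classify_field_preference(base, mk_maps(2, 2))
  expect_equal(p3$preference, 0)
  expect_equal(p3$category, "neutral")
})

test_that("firing preference is antisymmetric under context and k swap", {
  set.seed(56)
  for (i in 1:10) {
    r1 <- runif(1, 0.1, 5); r2 <- runif(1, 0.1, 5)
    fp <- function(a, b, k) (a - b) / (a + b) * (-1)^(k + 1)
    expect_equal(fp(r1, r2, 1), -fp(r2, r1, 2) * -1) # swap both: unchanged
    expect_equal(fp(r1, r2, 1), -fp(r1, r2, 2))      # swap k: sign flip
    expect_equal(fp(r1, r2, 1), -fp(r2, r1, 1))      # swap contexts: flip
  }
})

test_that("distance histograms count classes and flag long distances", {
  empty <- field_distance_histogram(tibble::tibble(), "discrimination")
  expect_equal(nrow(empty), 0)
  geom <- test_geometry()
  at_ports <- assign_reward_fields(
    tibble::tibble(center_x = reward_ports(geom)$x,
                   center_y = reward_ports(geom)$y), geom)
  h <- field_distance_histogram(at_ports, "discrimination")
  expect_equal(h$distance_class, "reward")
  expect_equal(h$n, 2L)
  # generalization: a single reward leaves room beyond 25 cm
  geng <- arena_geometry(paradigm = "generalization")
  far <- assign_reward_fields(tibble::tibble(center_x = 0, center_y = -17),
                              geng)
  hg <- field_distance_histogram(far, "generalization")
  expect_gt(sum(hg$n[suppressWarnings(
    as.numeric(sub("-.*", "", hg$distance_class))) >= 25], na.rm = TRUE), 0)
})

test_that("uniform centres in generalization give mass beyond 25 cm", {
  geng <- arena_geometry(paradigm = "generalization")
  set.seed(57)
  pts <- matrix(runif(4000, -20, 20), ncol = 2)
  pts <- pts[in_arena(pts, geng), ]
  rf <- assign_reward_fields(tibble::tibble(center_x = pts[, 1],
                                            center_y = pts[, 2]), geng)
  expect_gt(sum(rf$reward_distance > 25), 0)
})

test_that("the weighted GMM agrees with an unweighted oracle on resampled data", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(58)
  centers <- rbind(c(-8, -6), c(7, 8))
  xy <- expand.grid(x = seq(-16, 16, 2), y = seq(-16, 16, 2))
  w <- 10 * exp(-((xy$x - centers[1, 1])^2 + (xy$y - centers[1, 2])^2) / 18) +
    10 * exp(-((xy$x - centers[2, 1])^2 + (xy$y - centers[2, 2])^2) / 18)
  fit <- remapflow:::weighted_gmm(as.matrix(xy), w, centers + 1.5)
  # oracle: mclust on points resampled proportional to weight
  pts <- as.matrix(xy)[sample(nrow(xy), 4000, replace = TRUE,
                              prob = w / sum(w)), ]
  or <- mclust::Mclust(pts, G = 2, modelNames = "VVV", verbose = FALSE)
  est <- fit$mu[order(fit$mu[, 1]), ]
  ora <- t(or$parameters$mean)[order(t(or$parameters$mean)[, 1]), ]
  expect_lt(max(abs(est - ora)), 1)
})
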