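test_that("occupancy-weighted smoothing conserves total counts", {
  geom <- test_geometry()
  g <- remapflow:::map_grid(geom, 2)
  valid <- g$inside
  K <- remapflow:::smoothing_matrix(g, 3, valid)
  set.seed(40)
  counts <- rpois(g$nbin, 2) * valid
  expect_equal(sum(K %*% counts), sum(counts))
  expect_equal(colSums(K)[valid], rep(1, sum(valid)), ignore_attr = TRUE)
})

test_that("rate maps implement rate = events / occupancy on valid bins", {
  geom <- test_geometry()
  ses <- small_session()
  # near-delta smoothing isolates the definitional check in a single bin
  cfg <- remap_config(map_sigma = 1e-6)
  maps <- context_rate_maps(ses, neurons = 1, config = cfg)
  m <- maps[maps$context == "A", ]
  fr <- extract_analysis_frames(ses, mode = "spatial", config = cfg)
  af <- fr[fr$analysis & fr$context == "A", ]
  g <- remapflow:::map_grid(geom, cfg$bin_size)
  bins <- remapflow:::grid_index(ses$tracking$head_x[af$frame + 1],
                                 ses$tracking$head_y[af$frame + 1], g)
  ev <- ses$events$frame[ses$events$neuron == 1]
  evb <- bins[match(intersect(ev, af$frame), af$frame)]
  b <- evb[1]
  occ_min <- sum(bins == b) / 20 / 60
  expect_equal(m$rate[b], sum(evb == b) / occ_min)
  # occupancy column reports raw seconds
  expect_equal(m$occupancy[b], sum(bins == b) / 20)
})

test_that("zero-event neurons give all-zero valid maps", {
  ses <- small_session()
  maps <- context_rate_maps(ses, neurons = 999L)
  expect_true(all(maps$rate[maps$valid] == 0))
  expect_true(all(is.na(maps$rate[!maps$valid])))
})

test_that("stability is perfect for identical halves, undefined when constant", {
  # direct check of the correlation core used for split maps
  h <- list(valid = c(TRUE, TRUE, TRUE, FALSE), K = diag(4),
            denom_min = rep(1, 4))
  same <- cbind(c(1, 2, 3, 0))
  expect_equal(remapflow:::shared_cor(h, h, same, same), 1)
  const <- cbind(c(2, 2, 2, 0))
  expect_true(is.na(remapflow:::shared_cor(h, h, const, same)))
})

test_that("a planted stable place cell scores high, a Poisson cell low", {
  ses <- small_session()
  st <- stability_score(ses)
  place <- st[st$neuron == 1, ]
  bg <- st[st$neuron %in% 5:6, ]
  expect_gt(max(place$r_mean, na.rm = TRUE), 0.4)
  expect_lt(max(abs(bg$r_mean), na.rm = TRUE), 0.4)
  # Fisher z recorded monotonically
  expect_equal(sign(st$z_mean), sign(st$r_mean))
})

test_that("shuffle nulls are reproducible and centred near zero", {
  ses <- small_session()
  n1 <- event_shuffle_null(ses, neuron = 5, context = "A", n_shuffle = 40,
                           seed = 41)
  n2 <- event_shuffle_null(ses, neuron = 5, context = "A", n_shuffle = 40,
                           seed = 41)
  expect_identical(n1, n2)
  expect_lt(abs(mean(n1$r_mean, na.rm = TRUE)), 0.25)
  n3 <- event_shuffle_null(ses, neuron = 5, context = "A", n_shuffle = 40,
                           seed = 42)
  expect_false(identical(n1, n3))
})

test_that("the shuffle refuses spans shorter than two margins", {
  geom <- test_geometry()
  truth <- make_ground_truth(geom, n_background = 1, seed = 43)
  ses <- simulate_session(truth, geom, duration = 150, n_trials = 3,
                          seed = 44)
  expect_error(event_shuffle_null(ses, 1, "A", n_shuffle = 5, seed = 1),
               "too short")
})

test_that("place-cell classification applies all three criteria", {
  cfg <- remap_config()
  res <- tibble::tibble(
    neuron = c(1, 1, 2, 2, 3, 3),
    context = rep(c("A", "B"), 3),
    r_mean = c(0.9, 0.1, 0.9, 0.2, 0.38, 0.1),
    null95 = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3)
  )
  flags <- classify_place_cell(res, c(`1` = 50, `2` = 9, `3` = 50), cfg)
  expect_equal(flags$is_place_cell, c(TRUE, FALSE, FALSE))
})

test_that("full place-cell analysis flags planted cells and not noise", {
  ses <- small_session()
  pc <- place_cell_analysis(ses, n_shuffle = 100, seed = 45)
  flags <- dplyr::distinct(pc, neuron, is_place_cell)
  expect_true(all(flags$is_place_cell[flags$neuron %in% c(1, 2)]))
  expect_false(any(flags$is_place_cell[flags$neuron %in% c(5, 6)]))
})

test_that("remapping correlation is 1 for identical maps, ~0 for shuffled", {
  ses <- small_session()
  maps <- context_rate_maps(ses, neurons = 1)
  mapA <- maps[maps$context == "A", ]
  ident <- dplyr::bind_rows(mapA,
                            dplyr::mutate(mapA, context = "B"))
  expect_equal(remapping_correlation(ident)$r, 1)
  # permuting valid-bin rates destroys the correlation on average
  set.seed(46)
  rs <- replicate(40, {
    shuf <- mapA
    vi <- which(shuf$valid)
    shuf$rate[vi] <- shuf$rate[sample(vi)]
    both <- dplyr::bind_rows(mapA, dplyr::mutate(shuf, context = "B"))
    remapping_correlation(both)$r
  })
  expect_lt(mean(abs(rs)), 0.1)
  # symmetry
  mapsAB <- context_rate_maps(ses, neurons = 2)
  swapped <- dplyr::mutate(mapsAB,
                           context = ifelse(context == "A", "B", "A"))
  expect_equal(remapping_correlation(mapsAB)$r,
               remapping_correlation(swapped)$r)
})
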