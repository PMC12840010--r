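#' Calibration and recovery studies
#'
#' These functions run the package's standard simulation studies: each
#' generates synthetic sessions with planted ground truth, runs the full
#' analysis path under study, and reports recovery or calibration summaries.
#' They back the package's acceptance checks and are exported so the studies
#' can be rerun at other problem sizes.
#'
#' @name studies
NULL

#' Packaged demonstration session
#'
#' A small, fully reproducible 10-minute session used by the end-to-end
#' checks and the examples: two place cells, one directional cell, one
#' conjunctive cell and two background cells, run by a biased agent so that
#' correct, incorrect and timed-out trials all occur. The session definition
#' is fixed (seeded); it stands in for a recorded dataset.
#'
#' @param duration Session length in seconds (default 600).
#' @param seed Fixed seed of the packaged fixture (default 105).
#' @return A `remap_session`.
#' @export
demo_session <- function(duration = 600, seed = 105) {
  geom <- arena_geometry()
  truth <- dplyr::bind_rows(
    make_ground_truth(geom, n_place = 2, seed = 101),
    make_ground_truth(geom, n_directional = 1, n_conjunctive = 1, seed = 102),
    make_ground_truth(geom, n_background = 2, seed = 103)
  )
  truth$neuron <- seq_len(nrow(truth))
  simulate_session(truth, geom, duration = duration,
                   n_trials = round(duration / 33), seed = seed,
                   policy = "biased", p_correct = 0.7, p_timeout = 0.05)
}

#' Null calibration of the place-cell and directional-cell tests
#'
#' Simulates homogeneous-Poisson cells (no spatial or directional tuning,
#' 6 events/min) on a standard 40-minute session and measures the
#' false-positive rate of the place-cell classification and of the
#' directional-cell classification (stability + both shuffle nulls + index
#' rule). Maps use a reduced 4 cm resolution to keep the 500-shuffle nulls
#' fast.
#'
#' @param n_cells Number of simulated cells (default 200).
#' @param n_shuffle Shuffles per null (default 500).
#' @param seed Integer seed.
#' @param duration Session length in seconds (default 2400).
#' @return List with `place_fpr`, `dc_fpr`, `n_cells`.
#' @export
study_null_calibration <- function(n_cells = 200, n_shuffle = 500, seed = 1,
                                   duration = 2400) {
  geom <- arena_geometry()
  cfg <- remap_config(bin_size = 4)
  truth <- make_ground_truth(geom, n_background = n_cells,
                             seed = child_seed(seed, 1))
  ses <- simulate_session(truth, geom, duration = duration, n_trials = 70,
                          seed = child_seed(seed, 2), policy = "biased")
  frames <- extract_analysis_frames(ses, mode = "spatial", config = cfg)
  pc <- place_cell_analysis(ses, n_shuffle = n_shuffle,
                            seed = child_seed(seed, 3), config = cfg,
                            frames = frames)
  place_flags <- dplyr::distinct(pc, .data$neuron, .data$is_place_cell)
  dres <- directional_analysis(ses, n_shuffle = n_shuffle,
                               seed = child_seed(seed, 4), config = cfg,
                               frames = frames)
  dcls <- classify_directional_cells(dres, place_flags, config = cfg)
  list(place_fpr = mean(place_flags$is_place_cell),
       dc_fpr = mean(dcls$is_DC),
       n_cells = n_cells)
}

#' Place-field count and centre recovery
#'
#' Simulates place cells with 1-3 planted Gaussian fields at least 15 cm
#' apart on a shared 40-minute session, segments fields from the pooled
#' maps, and reports the fraction of cells with the correct field count and
#' the fraction of recovered fields whose centre lies within 3 cm of a
#' planted centre.
#'
#' @param n_cells Number of simulated place cells (default 100).
#' @param seed Integer seed.
#' @return List with `count_accuracy`, `center_within_3cm`, `n_cells`.
#' @export
study_field_recovery <- function(n_cells = 100, seed = 1) {
  geom <- arena_geometry()
  truth <- make_ground_truth(geom, n_place = n_cells, n_fields = 1:3,
                             seed = child_seed(seed, 1))
  ses <- simulate_session(truth, geom, duration = 2400, n_trials = 70,
                          seed = child_seed(seed, 2), policy = "biased")
  flds <- segment_place_fields(ses)
  truth_k <- vapply(truth$fields, nrow, integer(1))
  est_k <- vapply(truth$neuron, function(i) sum(flds$neuron == i), integer(1))
  errs <- unlist(lapply(truth$neuron, function(i) {
    tf <- truth$fields[[i]]
    ef <- flds[flds$neuron == i, ]
    if (!nrow(ef)) return(NULL)
    vapply(seq_len(nrow(ef)), function(j) {
      min(sqrt((tf$center_x - ef$center_x[j])^2 +
                 (tf$center_y - ef$center_y[j])^2))
    }, numeric(1))
  }))
  list(count_accuracy = mean(est_k == truth_k),
       center_within_3cm = mean(errs <= 3),
       n_cells = n_cells)
}

#' Spatial and rate remapping recovery
#'
#' Three planted populations on 40-minute sessions: a stable population
#' (same fields and gains in both contexts), a globally remapping population
#' (independent field locations per context), and rate-remapping populations
#' with per-context gain g in {1, 0.5, 0.2}. Reports the population median
#' between-context spatial correlations and, for each gain, the median field
#' rate overlap against the planted value 1 - |1-g|/(1+g).
#'
#' @param n_cells Cells per population (default 30).
#' @param seed Integer seed.
#' @return List with `median_r_stable`, `median_r_global`, and a tibble
#'   `gain_overlap` (`gain`, `expected`, `observed`, `abs_error`).
#' @export
study_remapping_recovery <- function(n_cells = 30, seed = 1) {
  geom <- arena_geometry()
  run_pop <- function(remapping, gain, s) {
    truth <- make_ground_truth(geom, n_place = n_cells, n_fields = 1:2,
                               remapping = remapping, gain = gain,
                               seed = child_seed(seed, s))
    simulate_session(truth, geom, duration = 2400, n_trials = 70,
                     seed = child_seed(seed, s + 1), policy = "biased")
  }
  ses_stable <- run_pop("none", c(1, 1), 10)
  ses_global <- run_pop("global", c(1, 1), 20)
  r_stable <- remapping_correlation(ses_stable)
  r_global <- remapping_correlation(ses_global)
  gains <- c(1, 0.5, 0.2)
  gain_overlap <- purrr::map_dfr(seq_along(gains), function(i) {
    g <- gains[i]
    ses <- run_pop("rate", c(1, g), 30 + 2 * i)
    flds <- segment_place_fields(ses)
    maps <- context_rate_maps(ses)
    fo <- field_rate_overlap(flds, maps)
    expected <- 1 - abs(1 - g) / (1 + g)
    observed <- stats::median(fo$overlap, na.rm = TRUE)
    tibble::tibble(gain = g, expected = expected, observed = observed,
                   abs_error = abs(observed - expected))
  })
  list(median_r_stable = stats::median(r_stable$r, na.rm = TRUE),
       median_r_global = stats::median(r_global$r, na.rm = TRUE),
       gain_overlap = gain_overlap)
}

#' Decoder calibration
#'
#' Three checks of the context decoder: (1) a globally remapping 50-cell,
#' 40-minute session, reporting the mean cross-validated accuracy under the
#' standard protocol; (2) a label-shuffled chance control repeated over
#' `n_shuffle_seeds` seeds on a context-balanced row subsample of a smaller
#' session (25 cells, 20 minutes; balancing pins chance at 0.5 rather than
#' at the majority-class fraction); and (3) a population in which only place
#' cells carry context information (rate-remapping place cells plus
#' context-blind background cells), comparing place-subset and
#' non-place-subset accuracies with the trial-blocked split, which measures
#' information content without letting near-duplicate window rows straddle
#' the train/test split.
#'
#' @param seed Integer seed.
#' @param n_shuffle_seeds Label-shuffle repetitions (default 20).
#' @return List with `cv_accuracy`, `shuffle_mean`, `shuffle_accuracies`,
#'   `place_accuracy`, `nonplace_accuracy`.
#' @export
study_decoder <- function(seed = 1, n_shuffle_seeds = 20) {
  geom <- arena_geometry()
  truth <- make_ground_truth(geom, n_place = 50, n_fields = 1:2,
                             remapping = "global", seed = child_seed(seed, 1))
  ses <- simulate_session(truth, geom, duration = 2400, n_trials = 70,
                          seed = child_seed(seed, 2), policy = "biased")
  mat <- build_decoder_frames(ses)
  main <- fit_context_decoder(mat, seed = child_seed(seed, 3))
  # label-shuffle control: balanced rows pin chance at 0.5
  truth_s <- make_ground_truth(geom, n_place = 25, n_fields = 1,
                               remapping = "global",
                               seed = child_seed(seed, 4))
  ses_s <- simulate_session(truth_s, geom, duration = 1200, n_trials = 35,
                            seed = child_seed(seed, 5), policy = "biased")
  mat_s <- build_decoder_frames(ses_s)
  mat_s <- with_seed(child_seed(seed, 6), {
    per_class <- min(min(table(mat_s$context)), 300)
    keep <- unlist(lapply(unique(mat_s$context), function(cc) {
      sample(which(mat_s$context == cc), per_class)
    }))
    mat_s[sort(keep), ]
  })
  shuffle_acc <- vapply(seq_len(n_shuffle_seeds), function(i) {
    fit_context_decoder(mat_s, seed = child_seed(seed, 10 + i),
                        shuffle_labels = TRUE)$cv_accuracy
  }, numeric(1))
  # only place cells carry context signal; trial-blocked split
  truth_p <- dplyr::bind_rows(
    make_ground_truth(geom, n_place = 25, n_fields = 1, remapping = "rate",
                      gain = c(1, 0.1), seed = child_seed(seed, 7)),
    make_ground_truth(geom, n_background = 25, seed = child_seed(seed, 8))
  )
  truth_p$neuron <- seq_len(nrow(truth_p))
  ses_p <- simulate_session(truth_p, geom, duration = 1800, n_trials = 52,
                            seed = child_seed(seed, 9), policy = "biased")
  place_flags <- tibble::tibble(
    neuron = truth_p$neuron,
    is_place_cell = truth_p$cell_class == "place"
  )
  sub <- decode_by_subset(ses_p, place_flags, trial_subsets = "all",
                          seed = child_seed(seed, 10), blocked_split = TRUE)
  list(cv_accuracy = main$cv_accuracy,
       shuffle_mean = mean(shuffle_acc),
       shuffle_accuracies = shuffle_acc,
       place_accuracy = sub$cv_accuracy[sub$cell_subset == "place"],
       nonplace_accuracy = sub$cv_accuracy[sub$cell_subset == "nonplace"])
}

#' Directional disambiguation study
#'
#' Sensitivity: von Mises directional cells (kappa = 2, modulation depth
#' 0.8, no place field) should be classified as directionally modulated
#' cells. Specificity: pure place cells with fields near the walls on a
#' wall-biased trajectory (occupancy-induced spurious directional tuning)
#' should not. Reports the fraction classified DC in each population.
#'
#' @param n_cells Cells per population (default 30).
#' @param n_shuffle Shuffles per null (default 500).
#' @param seed Integer seed.
#' @return List with `dc_sensitivity`, `dc_specificity_error` (fraction of
#'   pure place cells classified DC), `n_cells`.
#' @export
study_directional <- function(n_cells = 30, n_shuffle = 500, seed = 1) {
  geom <- arena_geometry()
  truth_d <- make_ground_truth(geom, n_directional = n_cells,
                               seed = child_seed(seed, 1))
  ses_d <- simulate_session(truth_d, geom, duration = 2400, n_trials = 70,
                            seed = child_seed(seed, 2), policy = "biased")
  dres_d <- directional_analysis(ses_d, n_shuffle = n_shuffle,
                                 seed = child_seed(seed, 3))
  dc_d <- classify_directional_cells(dres_d)
  truth_p <- make_ground_truth(geom, n_place = n_cells, n_fields = 1,
                               near_wall = TRUE, seed = child_seed(seed, 4))
  ses_p <- simulate_session(truth_p, geom, duration = 2400, n_trials = 70,
                            seed = child_seed(seed, 5), policy = "biased",
                            motion = list(wall_bias = 0.7))
  dres_p <- directional_analysis(ses_p, n_shuffle = n_shuffle,
                                 seed = child_seed(seed, 6))
  dc_p <- classify_directional_cells(dres_p)
  list(dc_sensitivity = mean(dc_d$is_DC),
       dc_specificity_error = mean(dc_p$is_DC),
       n_cells = n_cells)
}
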