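#' Build the decoder frame matrix
#'
#' The per-cell calcium event series (at the 20 Hz master clock) is smoothed
#' by summing events over non-overlapping 60-frame windows aligned to
#' session start, every frame carrying its window's sum. The series is then
#' restricted to foraging frames (locomotion and rest), and finally thinned
#' to every 20th retained frame (1 sample/s).
#'
#' @param session A `remap_session`.
#' @param frames Optional precomputed decoding-mode frames table from
#'   [extract_analysis_frames()].
#' @param neurons Neuron ids forming the columns (default all neurons with
#'   events).
#' @param trial_subset `"all"` or `"correct"` (restrict rows to correct
#'   trials before thinning).
#' @param config A [remap_config()].
#' @return A tibble with one row per retained frame: `frame`, `trial`,
#'   `context`, `outcome`, then one integer column `n<id>` per neuron.
#' @export
build_decoder_frames <- function(session, frames = NULL, neurons = NULL,
                                 trial_subset = c("all", "correct"),
                                 config = remap_config()) {
  trial_subset <- match.arg(trial_subset)
  if (is.null(frames)) {
    frames <- extract_analysis_frames(session, mode = "decoding",
                                      config = config)
  }
  if (is.null(neurons)) neurons <- sort(unique(session$events$neuron))
  if (!length(neurons)) stop("empty neuron subset", call. = FALSE)
  keep <- frames[frames$analysis, ]
  if (trial_subset == "correct") keep <- keep[keep$outcome == "correct", ]
  keep <- keep[order(keep$frame), ]
  thin <- keep[seq(1, nrow(keep), by = config$decoder_thin), ]
  win_of <- function(fr) fr %/% config$decoder_window
  wins <- win_of(thin$frame)
  ev_by <- split(session$events$frame, session$events$neuron)
  cols <- lapply(neurons, function(id) {
    ev <- ev_by[[as.character(id)]] %||% integer()
    cnt <- table(factor(win_of(ev),
                        levels = sort(unique(wins))))
    as.integer(cnt[as.character(wins)])
  })
  names(cols) <- paste0("n", neurons)
  out <- tibble::tibble(frame = thin$frame, trial = thin$trial,
                        context = thin$context, outcome = thin$outcome)
  dplyr::bind_cols(out, tibble::as_tibble(cols))
}

#' Fit the context decoder
#'
#' Trains a support vector machine with a radial basis function kernel on
#' the decoder frame matrix to predict context. Columns are standardized
#' (z score); rows are split 80/20 into training and held-out sets by a
#' seeded stratified random draw; the kernel scale is tuned by 20-fold
#' cross-validation on the training portion over a 9-point logarithmic grid
#' centred on the median-pairwise-distance heuristic; the regularization
#' parameter is fixed at 1. Reported are the mean cross-validated accuracy
#' of the selected kernel scale and the held-out accuracy.
#'
#' @param matrix_tbl Tibble from [build_decoder_frames()].
#' @param seed Integer seed (split, fold assignment, label shuffling).
#' @param shuffle_labels If `TRUE`, context labels are randomly permuted
#'   before fitting (chance-level control).
#' @param blocked_split If `TRUE`, the 80/20 split and the cross-validation
#'   folds hold out whole trials instead of random rows (methodological
#'   comparison; default `FALSE`, the random-row split of the standard
#'   protocol).
#' @param config A [remap_config()].
#' @return A one-row tibble of class `remap_decoding`: `cv_accuracy`,
#'   `holdout_accuracy`, `kernel_scale`, `n_rows`, `n_cells`, `seed`.
#' @export
fit_context_decoder <- function(matrix_tbl, seed = NULL,
                                shuffle_labels = FALSE,
                                blocked_split = FALSE,
                                config = remap_config()) {
  feat <- as.matrix(matrix_tbl[grep("^n", names(matrix_tbl))])
  y <- factor(matrix_tbl$context)
  if (nlevels(y) < 2) stop("need both context labels", call. = FALSE)
  if (nrow(feat) < 40) {
    stop("too few rows for an 80/20 split with 20-fold cross-validation",
         call. = FALSE)
  }
  keep_col <- apply(feat, 2, stats::sd) > 0
  if (!all(keep_col)) {
    warning(sum(!keep_col), " constant cell column(s) dropped", call. = FALSE)
    feat <- feat[, keep_col, drop = FALSE]
  }
  with_seed(seed, {
    if (shuffle_labels) y <- sample(y)
    n <- nrow(feat)
    if (blocked_split) {
      trials <- unique(matrix_tbl$trial)
      te_tr <- sample(trials, max(1, round(length(trials) * (1 - config$train_fraction))))
      test_idx <- which(matrix_tbl$trial %in% te_tr)
    } else {
      test_idx <- unlist(lapply(levels(y), function(lv) {
        rows <- which(y == lv)
        sample(rows, round(length(rows) * (1 - config$train_fraction)))
      }))
    }
    train_idx <- setdiff(seq_len(n), test_idx)
    Xtr <- feat[train_idx, , drop = FALSE]
    ytr <- y[train_idx]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(feat[test_idx, , drop = FALSE], 2, mu), 2, sdv, "/")
    # kernel-scale grid around the median pairwise distance heuristic
    sub <- Xtr[sample(nrow(Xtr), min(200, nrow(Xtr))), , drop = FALSE]
    med <- stats::median(stats::dist(sub))
    if (!is.finite(med) || med <= 0) med <- sqrt(ncol(Xtr))
    scales <- med * 10^seq(-2, 2, length.out = 9)
    folds <- if (blocked_split) {
      make_folds_blocked(matrix_tbl$trial[train_idx], config$cv_folds)
    } else {
      make_folds(ytr, config$cv_folds)
    }
    cv_acc <- vapply(scales, function(s) {
      gamma <- 1 / (2 * s^2)
      accs <- vapply(seq_len(config$cv_folds), function(f) {
        tr <- folds != f
        if (all(tr) || length(unique(ytr[tr])) < 2) return(NA_real_)
        fit <- e1071::svm(Xtr[tr, , drop = FALSE], ytr[tr],
                          kernel = "radial", gamma = gamma,
                          cost = config$svm_cost, scale = FALSE)
        mean(stats::predict(fit, Xtr[!tr, , drop = FALSE]) == ytr[!tr])
      }, numeric(1))
      mean(accs, na.rm = TRUE)
    }, numeric(1))
    best <- which.max(cv_acc)
    fit <- e1071::svm(Xtr, ytr, kernel = "radial",
                      gamma = 1 / (2 * scales[best]^2),
                      cost = config$svm_cost, scale = FALSE)
    holdout <- mean(stats::predict(fit, Xte) == y[test_idx])
    out <- tibble::tibble(cv_accuracy = cv_acc[best],
                          holdout_accuracy = holdout,
                          kernel_scale = scales[best],
                          n_rows = n, n_cells = ncol(feat),
                          seed = seed %||% NA_integer_)
    class(out) <- c("remap_decoding", class(out))
    out
  })
}

# stratified fold assignment
make_folds <- function(y, k) {
  folds <- integer(length(y))
  for (lv in levels(y)) {
    rows <- which(y == lv)
    folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  folds
}

# fold assignment keeping all rows of one trial in the same fold
make_folds_blocked <- function(trial, k) {
  ids <- unique(trial)
  fold_of <- stats::setNames(sample(rep_len(seq_len(k), length(ids))), ids)
  as.integer(fold_of[as.character(trial)])
}

#' Decode context by cell and trial subsets
#'
#' Runs the context decoder for the three cell subsets (all cells, place
#' cells only, non-place cells only) crossed with trial subsets (all trials,
#' correct trials only), with a common seed. Empty subsets are skipped with
#' a message.
#'
#' @param session A `remap_session`.
#' @param place_cells Tibble with `neuron`, `is_place_cell`.
#' @param trial_subsets Character vector among `"all"`, `"correct"`.
#' @param seed Integer seed shared by all fits.
#' @param blocked_split Use the trial-blocked 80/20 split (see
#'   [fit_context_decoder()]); recommended when comparing information
#'   content between subsets, since the random-row split lets near-duplicate
#'   window rows straddle the split.
#' @param config A [remap_config()].
#' @param frames Optional precomputed decoding-mode frames table.
#' @return Tibble with one row per (cell subset, trial subset) fit and the
#'   columns of [fit_context_decoder()] plus `cell_subset`, `trial_subset`.
#' @export
decode_by_subset <- function(session, place_cells,
                             trial_subsets = c("all", "correct"),
                             seed = NULL, blocked_split = FALSE,
                             config = remap_config(),
                             frames = NULL) {
  if (is.null(frames)) {
    frames <- extract_analysis_frames(session, mode = "decoding",
                                      config = config)
  }
  pc <- dplyr::distinct(place_cells, .data$neuron, .data$is_place_cell)
  all_ids <- sort(unique(session$events$neuron))
  subsets <- list(
    all = all_ids,
    place = intersect(all_ids, pc$neuron[pc$is_place_cell]),
    nonplace = setdiff(all_ids, pc$neuron[pc$is_place_cell])
  )
  grid <- expand.grid(cell_subset = names(subsets),
                      trial_subset = trial_subsets,
                      stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    ids <- subsets[[grid$cell_subset[i]]]
    if (!length(ids)) {
      message("cell subset '", grid$cell_subset[i], "' is empty; skipped")
      return(NULL)
    }
    mat <- build_decoder_frames(session, frames, neurons = ids,
                                trial_subset = grid$trial_subset[i],
                                config = config)
    res <- fit_context_decoder(mat, seed = seed,
                               blocked_split = blocked_split, config = config)
    dplyr::bind_cols(tibble::tibble(cell_subset = grid$cell_subset[i],
                                    trial_subset = grid$trial_subset[i]), res)
  })
}
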