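# ---- internal spatial machinery ------------------------------------------
#
# All map-based statistics run off a per-session "prep" object built once:
# for each context, the concatenated sequence of spatial analysis frames
# (running frames of the foraging phases, in time order), the spatial bin of
# each such frame, trial-half assignments for the two split rules, raw and
# smoothed occupancy per half, bin validity masks and the Gaussian smoothing
# operators restricted to the valid bins.

spatial_prep <- function(session, config = remap_config(), frames = NULL) {
  if (is.null(frames)) {
    frames <- extract_analysis_frames(session, mode = "spatial",
                                      config = config)
  }
  g <- map_grid(session$geometry, config$bin_size)
  fr_min <- config$frame_rate * 60   # frames per minute
  build_half <- function(binseq, members) {
    occ <- tabulate(binseq[members], nbins = g$nbin)
    valid <- g$inside & (occ / config$frame_rate >= config$min_occupancy)
    K <- smoothing_matrix(g, config$map_sigma, valid)
    denom_min <- as.numeric(K %*% occ) / fr_min  # smoothed occupancy, minutes
    list(occ = occ, valid = valid, K = K, denom_min = denom_min)
  }
  ctxs <- session$geometry$contexts
  prep_ctx <- lapply(ctxs, function(cc) {
    af <- frames[frames$analysis & frames$context == cc, ]
    if (!nrow(af)) return(NULL)
    binseq <- grid_index(session$tracking$head_x[af$frame + 1L],
                         session$tracking$head_y[af$frame + 1L], g)
    trial_list <- unique(af$trial)
    trial_pos <- match(af$trial, trial_list)
    half_time <- ifelse(trial_pos <= ceiling(length(trial_list) / 2), 1L, 2L)
    half_par <- ifelse(trial_pos %% 2L == 1L, 1L, 2L)
    posmap <- rep(NA_integer_, session$n_frames)
    posmap[af$frame + 1L] <- seq_len(nrow(af))
    list(
      context = cc, frames = af$frame, n = nrow(af), bin = binseq,
      posmap = posmap, half_time = half_time, half_par = half_par,
      full = build_half(binseq, rep(TRUE, nrow(af))),
      t1 = build_half(binseq, half_time == 1L),
      t2 = build_half(binseq, half_time == 2L),
      p1 = build_half(binseq, half_par == 1L),
      p2 = build_half(binseq, half_par == 2L)
    )
  })
  names(prep_ctx) <- ctxs
  list(g = g, ctx = prep_ctx, config = config)
}

# smoothed rate map (events/min) of a count vector on one half
half_rate <- function(half, counts) {
  r <- as.numeric(half$K %*% counts)
  out <- rep(NA_real_, length(r))
  out[half$valid] <- r[half$valid] / half$denom_min[half$valid]
  out
}

# correlation of matched columns of two matrices; NA when either is constant
col_cor <- function(A, B) {
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  num <- colSums(A * B)
  den <- sqrt(colSums(A^2) * colSums(B^2))
  ifelse(den > 0, num / den, NA_real_)
}

# split correlations (time halves and parity halves) for count matrices whose
# columns are replicates (shuffles); counts given for each half separately
split_cor <- function(cx, Ct1, Ct2, Cp1, Cp2) {
  rt <- shared_cor(cx$t1, cx$t2, Ct1, Ct2)
  rp <- shared_cor(cx$p1, cx$p2, Cp1, Cp2)
  (rt + rp) / 2
}

shared_cor <- function(h1, h2, C1, C2) {
  m <- h1$valid & h2$valid
  if (sum(m) < 2) return(rep(NA_real_, ncol(C1)))
  R1 <- (h1$K %*% C1)[m, , drop = FALSE] / h1$denom_min[m]
  R2 <- (h2$K %*% C2)[m, , drop = FALSE] / h2$denom_min[m]
  col_cor(R1, R2)
}

# event positions of one neuron within a context's concatenated frame sequence
ctx_positions <- function(cx, event_frames) {
  p <- cx$posmap[event_frames + 1L]
  p[!is.na(p)]
}

# counts per half for a set of sequence positions
half_counts <- function(cx, pos) {
  b <- cx$bin[pos]
  list(
    t1 = tabulate(b[cx$half_time[pos] == 1L], nbins = length(cx$full$occ)),
    t2 = tabulate(b[cx$half_time[pos] == 2L], nbins = length(cx$full$occ)),
    p1 = tabulate(b[cx$half_par[pos] == 1L], nbins = length(cx$full$occ)),
    p2 = tabulate(b[cx$half_par[pos] == 2L], nbins = length(cx$full$occ))
  )
}

obs_stability <- function(cx, pos) {
  hc <- half_counts(cx, pos)
  rt <- shared_cor(cx$t1, cx$t2, cbind(hc$t1), cbind(hc$t2))
  rp <- shared_cor(cx$p1, cx$p2, cbind(hc$p1), cbind(hc$p2))
  c(r_split = rt, r_evenodd = rp, r_mean = (rt + rp) / 2)
}

# circular-shift null of r_mean, vectorized over shuffles
null_stability <- function(cx, pos, n_shuffle, seed, config) {
  margin <- round(config$shuffle_margin * config$frame_rate)
  if (cx$n <= 2 * margin) {
    stop("analysis-frame span too short for the circular shuffle",
         call. = FALSE)
  }
  nb <- length(cx$full$occ)
  with_seed(seed, {
    offs <- sample(seq.int(margin, cx$n - margin), n_shuffle, replace = TRUE)
    Ct1 <- Ct2 <- Cp1 <- Cp2 <- matrix(0L, nb, n_shuffle)
    for (s in seq_len(n_shuffle)) {
      p2 <- ((pos - 1L + offs[s]) %% cx$n) + 1L
      b <- cx$bin[p2]
      ht <- cx$half_time[p2]
      hp <- cx$half_par[p2]
      Ct1[, s] <- tabulate(b[ht == 1L], nbins = nb)
      Ct2[, s] <- tabulate(b[ht == 2L], nbins = nb)
      Cp1[, s] <- tabulate(b[hp == 1L], nbins = nb)
      Cp2[, s] <- tabulate(b[hp == 2L], nbins = nb)
    }
    split_cor(cx, Ct1, Ct2, Cp1, Cp2)
  })
}

# ---- exported surface -----------------------------------------------------

#' Context rate maps of one or more neurons
#'
#' Calcium events and head position during the running epochs of the foraging
#' phases are concatenated per context; position is binned into 2x2 cm bins
#' and both the event-count and occupancy grids are smoothed with a Gaussian
#' kernel (sigma = 3 cm) restricted to the valid bins (inside the octagon,
#' raw occupancy at least 0.1 s) before division, giving event rates in
#' events/min.
#'
#' @param session A `remap_session`.
#' @param neurons Neuron ids (default: all neurons with events).
#' @param config A [remap_config()].
#' @param frames Optional precomputed [extract_analysis_frames()] table
#'   (spatial mode).
#' @param pooled If `TRUE`, additionally return a `"pooled"` context with the
#'   events of both contexts pooled (used for field segmentation).
#' @return Tibble with columns `neuron`, `context`, `x`, `y` (bin centres,
#'   cm), `rate` (events/min, `NA` on invalid bins), `occupancy` (raw
#'   seconds) and `valid`.
#' @export
context_rate_maps <- function(session, neurons = NULL,
                              config = remap_config(), frames = NULL,
                              pooled = FALSE) {
  prep <- spatial_prep(session, config, frames)
  rate_maps_from_prep(session, prep, neurons, pooled)
}

rate_maps_from_prep <- function(session, prep, neurons = NULL,
                                pooled = FALSE) {
  if (is.null(neurons)) neurons <- sort(unique(session$events$neuron))
  g <- prep$g
  ev_by <- split(session$events$frame, session$events$neuron)
  one_ctx <- function(cx, label, id) {
    ev <- ev_by[[as.character(id)]] %||% integer()
    pos <- ctx_positions(cx, ev)
    counts <- tabulate(cx$bin[pos], nbins = g$nbin)
    tibble::tibble(neuron = id, context = label,
                   x = g$centers_x, y = g$centers_y,
                   rate = half_rate(cx$full, counts),
                   occupancy = cx$full$occ / prep$config$frame_rate,
                   valid = cx$full$valid)
  }
  out <- purrr::map_dfr(neurons, function(id) {
    dplyr::bind_rows(purrr::imap(prep$ctx, function(cx, label) {
      if (is.null(cx)) return(NULL)
      one_ctx(cx, label, id)
    }))
  })
  if (pooled) {
    pl <- pooled_prep(prep)
    pooled_rows <- purrr::map_dfr(neurons, function(id) {
      one_ctx(pl, "pooled", id)
    })
    out <- dplyr::bind_rows(out, pooled_rows)
  }
  out
}

# a pseudo-context pooling all contexts' analysis frames (for field maps)
pooled_prep <- function(prep) {
  cxs <- prep$ctx[!vapply(prep$ctx, is.null, logical(1))]
  g <- prep$g
  binseq <- unlist(lapply(cxs, `[[`, "bin"), use.names = FALSE)
  frames <- unlist(lapply(cxs, `[[`, "frames"), use.names = FALSE)
  ord <- order(frames)
  binseq <- binseq[ord]; frames <- frames[ord]
  occ <- tabulate(binseq, nbins = g$nbin)
  valid <- g$inside &
    (occ / prep$config$frame_rate >= prep$config$min_occupancy)
  K <- smoothing_matrix(g, prep$config$map_sigma, valid)
  posmap <- rep(NA_integer_, length(cxs[[1]]$posmap))
  posmap[frames + 1L] <- seq_along(frames)
  list(context = "pooled", frames = frames, n = length(frames),
       bin = binseq, posmap = posmap,
       full = list(occ = occ, valid = valid, K = K,
                   denom_min = as.numeric(K %*% occ) /
                     (prep$config$frame_rate * 60)))
}

#' Split-half spatial stability of neurons
#'
#' For each context map, the trials of the context are split into first vs
#' second half (in time) and into even vs odd trials; rate maps are rebuilt
#' per split and the Pearson correlation over bins valid in both half-maps is
#' computed. The stability score is the mean of the two correlations; its
#' Fisher z transform is reported alongside. Undefined correlations (fewer
#' than two shared valid bins, or a constant half-map) propagate as `NA`.
#'
#' @inheritParams context_rate_maps
#' @return Tibble with columns `neuron`, `context`, `n_events` (events in the
#'   context's analysis frames), `r_split`, `r_evenodd`, `r_mean`, `z_mean`.
#' @export
stability_score <- function(session, neurons = NULL,
                            config = remap_config(), frames = NULL) {
  prep <- spatial_prep(session, config, frames)
  stability_from_prep(session, prep, neurons)
}

stability_from_prep <- function(session, prep, neurons = NULL) {
  if (is.null(neurons)) neurons <- sort(unique(session$events$neuron))
  ev_by <- split(session$events$frame, session$events$neuron)
  purrr::map_dfr(neurons, function(id) {
    ev <- ev_by[[as.character(id)]] %||% integer()
    dplyr::bind_rows(purrr::imap(prep$ctx, function(cx, label) {
      if (is.null(cx)) return(NULL)
      pos <- ctx_positions(cx, ev)
      st <- obs_stability(cx, pos)
      tibble::tibble(neuron = id, context = label, n_events = length(pos),
                     r_split = st[["r_split"]], r_evenodd = st[["r_evenodd"]],
                     r_mean = st[["r_mean"]], z_mean = atanh(pmin(pmax(
                       st[["r_mean"]], -1 + 1e-12), 1 - 1e-12)))
    }))
  })
}

#' Circular-shuffle null distribution of spatial stability
#'
#' Event positions within the concatenated context frame sequence are
#' circularly shifted by a uniform random offset at least 1 min away from the
#' original timepoints (and at most the sequence length minus 1 min), and the
#' split-half stability score is recomputed, 500 times by default.
#'
#' @param session A `remap_session`.
#' @param neuron A single neuron id.
#' @param context Context label.
#' @param n_shuffle Number of shuffles (default from `config`).
#' @param seed Integer seed.
#' @param config A [remap_config()].
#' @param frames Optional precomputed spatial-mode frames table.
#' @return Tibble with columns `shuffle` and `r_mean`.
#' @export
event_shuffle_null <- function(session, neuron, context, n_shuffle = NULL,
                               seed = NULL, config = remap_config(),
                               frames = NULL) {
  n_shuffle <- n_shuffle %||% config$n_shuffle
  prep <- spatial_prep(session, config, frames)
  cx <- prep$ctx[[context]]
  if (is.null(cx)) stop("no analysis frames in context ", context, call. = FALSE)
  ev <- session$events$frame[session$events$neuron == neuron]
  pos <- ctx_positions(cx, ev)
  tibble::tibble(shuffle = seq_len(n_shuffle),
                 r_mean = null_stability(cx, pos, n_shuffle, seed, config))
}

#' Identify place cells
#'
#' Runs the full place-cell test for every neuron: split-half stability per
#' context, a circular event-shuffle null distribution (500 shuffles per
#' context), and classification. A neuron is a place cell when its stability
#' exceeds both the 95th percentile of its null distribution and the absolute
#' 0.4 floor in at least one context, and it fired at least 10 events in the
#' session.
#'
#' @inheritParams context_rate_maps
#' @param n_shuffle Shuffles per neuron and context (default from `config`).
#' @param seed Integer seed for the shuffle offsets.
#' @return Tibble with one row per neuron and context: `neuron`, `context`,
#'   `n_events`, `r_split`, `r_evenodd`, `r_mean`, `z_mean`, `null95`,
#'   `pass` (this context's criterion) and `is_place_cell` (neuron-level
#'   flag, identical across the neuron's rows).
#' @examples
#' geom <- arena_geometry()
#' tr <- make_ground_truth(geom, n_place = 1, n_background = 1, seed = 2)
#' ses <- simulate_session(tr, geom, duration = 600, n_trials = 20, seed = 2)
#' pc <- place_cell_analysis(ses, n_shuffle = 50, seed = 3)
#' @export
place_cell_analysis <- function(session, neurons = NULL, n_shuffle = NULL,
                                seed = NULL, config = remap_config(),
                                frames = NULL) {
  n_shuffle <- n_shuffle %||% config$n_shuffle
  prep <- spatial_prep(session, config, frames)
  if (is.null(neurons)) neurons <- sort(unique(session$events$neuron))
  ev_by <- split(session$events$frame, session$events$neuron)
  total <- vapply(as.character(neurons),
                  function(k) length(ev_by[[k]] %||% integer()), integer(1))
  res <- purrr::map_dfr(seq_along(neurons), function(i) {
    id <- neurons[i]
    ev <- ev_by[[as.character(id)]] %||% integer()
    dplyr::bind_rows(purrr::imap(prep$ctx, function(cx, label) {
      if (is.null(cx)) return(NULL)
      pos <- ctx_positions(cx, ev)
      st <- obs_stability(cx, pos)
      nul <- null_stability(cx, pos, n_shuffle,
                            child_seed(seed, i * 2L + match(label, names(prep$ctx))),
                            prep$config)
      q95 <- stats::quantile(nul, prep$config$null_quantile, na.rm = TRUE,
                             names = FALSE)
      tibble::tibble(neuron = id, context = label, n_events = length(pos),
                     r_split = st[["r_split"]], r_evenodd = st[["r_evenodd"]],
                     r_mean = st[["r_mean"]],
                     z_mean = atanh(pmin(pmax(st[["r_mean"]], -1 + 1e-12),
                                         1 - 1e-12)),
                     null95 = q95,
                     pass = !is.na(st[["r_mean"]]) && !is.na(q95) &&
                       st[["r_mean"]] > q95 &&
                       st[["r_mean"]] > prep$config$stability_floor)
    }))
  })
  res |>
    dplyr::group_by(.data$neuron) |>
    dplyr::mutate(total_events = total[as.character(.data$neuron[1])],
                  is_place_cell = any(.data$pass) &&
                    .data$total_events[1] >= prep$config$min_events) |>
    dplyr::ungroup()
}

#' Classify place cells from precomputed per-context results
#'
#' Applies the classification rule to a table of per-context stability and
#' null results: place cell iff (`r_mean` > `null95` and `r_mean` > 0.4) in
#' at least one context and `total_events` >= 10.
#'
#' @param results Data frame with columns `neuron`, `r_mean`, `null95`.
#' @param total_events Named or positional vector of session event counts per
#'   neuron (single value recycled).
#' @param config A [remap_config()].
#' @return Tibble with `neuron` and `is_place_cell`.
#' @export
classify_place_cell <- function(results, total_events,
                                config = remap_config()) {
  ids <- unique(results$neuron)
  if (length(total_events) == 1) {
    total_events <- stats::setNames(rep(total_events, length(ids)), ids)
  }
  if (is.null(names(total_events))) names(total_events) <- ids
  results |>
    dplyr::group_by(neuron = .data$neuron) |>
    dplyr::summarise(is_place_cell = any(
      !is.na(.data$r_mean) & !is.na(.data$null95) &
        .data$r_mean > .data$null95 &
        .data$r_mean > config$stability_floor
    ) && total_events[as.character(.data$neuron[1])] >= config$min_events,
    .groups = "drop")
}

#' Between-context spatial (remapping) correlation
#'
#' Pearson correlation between the two smoothed context rate maps of each
#' neuron over bins valid in both, requiring at least 10 shared bins. High
#' values indicate preserved spatial maps; low values indicate global
#' remapping.
#'
#' @param maps Tibble from [context_rate_maps()] (both contexts present), or
#'   a `remap_session` (maps are then computed internally).
#' @param config A [remap_config()] (used only when `maps` is a session).
#' @return Tibble with columns `neuron`, `n_bins` (shared valid bins) and
#'   `r` (`NA` if fewer than 10 shared bins or a constant map).
#' @export
remapping_correlation <- function(maps, config = remap_config()) {
  if (inherits(maps, "remap_session")) {
    maps <- context_rate_maps(maps, config = config)
  }
  ctxs <- setdiff(unique(maps$context), "pooled")
  stopifnot(length(ctxs) == 2)
  wide <- maps |>
    dplyr::filter(.data$context %in% ctxs) |>
    dplyr::mutate(context = ifelse(.data$context == ctxs[1], "m1", "m2")) |>
    tidyr::pivot_wider(id_cols = c("neuron", "x", "y"),
                       names_from = "context",
                       values_from = c("rate", "valid"))
  wide |>
    dplyr::group_by(neuron = .data$neuron) |>
    dplyr::summarise(
      n_bins = sum(.data$valid_m1 & .data$valid_m2),
      r = {
        m <- .data$valid_m1 & .data$valid_m2
        if (sum(m) < 10) NA_real_ else {
          a <- .data$rate_m1[m]; b <- .data$rate_m2[m]
          if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else
            stats::cor(a, b)
        }
      },
      .groups = "drop")
}
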