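#' Relative running direction to a reference point
#'
#' The head position is smoothed with the 167 ms moving average; the
#' allocentric heading \eqn{\varphi_i} is the quadrant-aware arctangent of
#' the frame-to-frame head displacement, the bearing \eqn{a_i} is the
#' quadrant-aware arctangent from the head to the reference point
#' \eqn{(R_X, R_Y)}, and the relative running direction is
#' \eqn{H_i = ((\varphi_i - a_i + \pi) \bmod 2\pi) - \pi \in [-\pi, \pi)}.
#' Frames with zero displacement have undefined heading and are dropped.
#'
#' @param tracking Tracking tibble (columns `frame`, `head_x`, `head_y`).
#' @param reference Numeric length-2 reference point \eqn{(R_X, R_Y)} in cm.
#' @param config A [remap_config()].
#' @return Tibble with columns `frame`, `phi`, `bearing`, `H` for frames with
#'   defined heading.
#' @examples
#' trk <- tibble::tibble(frame = 0:2, head_x = c(0, 0, 0),
#'                       head_y = c(-10, -9, -8))
#' relative_running_direction(trk, reference = c(0, 0),
#'                            config = remap_config(speed_smooth_ms = 1))
#' @export
relative_running_direction <- function(tracking, reference = c(0, 0),
                                       config = remap_config()) {
  w <- smooth_window(config)
  hx <- moving_average(tracking$head_x, w)
  hy <- moving_average(tracking$head_y, w)
  n <- length(hx)
  dx <- c(diff(hx), NA_real_)
  dy <- c(diff(hy), NA_real_)
  phi <- ifelse(!is.na(dx) & (dx != 0 | dy != 0), atan2(dy, dx), NA_real_)
  bearing <- atan2(reference[2] - hy, reference[1] - hx)
  out <- tibble::tibble(frame = col_or(tracking, "frame", seq_len(n) - 1L),
                        phi = phi, bearing = bearing,
                        H = wrap_angle(phi - bearing))
  out[!is.na(out$H), ]
}

# ---- internal directional machinery --------------------------------------
#
# Per context: the sequence of running foraging frames with defined H, the
# 45-degree direction bin of each frame, the spatial bin (for the joint
# occupancy p(x, y, H)), occupancy time per direction bin (full session and
# per split half), and the event-position map. Direction bins are centred on
# the wall-normal angles (bin b centre = (b - 1) * 45 degrees).

directional_prep <- function(session, config = remap_config(), frames = NULL,
                             reference = NULL) {
  if (is.null(frames)) {
    frames <- extract_analysis_frames(session, mode = "spatial",
                                      config = config)
  }
  reference <- reference %||% session$geometry$reference
  g <- map_grid(session$geometry, config$bin_size)
  H_tab <- relative_running_direction(session$tracking, reference, config)
  Hmap <- rep(NA_real_, session$n_frames)
  Hmap[H_tab$frame + 1L] <- H_tab$H
  nb_dir <- config$direction_bins
  fr_min <- config$frame_rate * 60
  ctxs <- session$geometry$contexts
  prep_ctx <- lapply(ctxs, function(cc) {
    af <- frames[frames$analysis & frames$context == cc, ]
    if (!nrow(af)) return(NULL)
    H <- Hmap[af$frame + 1L]
    keep <- !is.na(H)
    af <- af[keep, ]; H <- H[keep]
    if (!nrow(af)) return(NULL)
    dirbin <- angle_to_wall(H) + 1L
    sbin <- grid_index(session$tracking$head_x[af$frame + 1L],
                       session$tracking$head_y[af$frame + 1L], g)
    trial_list <- unique(af$trial)
    trial_pos <- match(af$trial, trial_list)
    half_time <- ifelse(trial_pos <= ceiling(length(trial_list) / 2), 1L, 2L)
    half_par <- ifelse(trial_pos %% 2L == 1L, 1L, 2L)
    posmap <- rep(NA_integer_, session$n_frames)
    posmap[af$frame + 1L] <- seq_len(nrow(af))
    occ_min <- function(memb) tabulate(dirbin[memb], nbins = nb_dir) / fr_min
    # joint occupancy p(x, y, H): frame counts per (spatial bin, dir bin)
    P <- matrix(0, g$nbin, nb_dir)
    tb <- table(factor(sbin, levels = seq_len(g$nbin)),
                factor(dirbin, levels = seq_len(nb_dir)))
    P[] <- as.numeric(tb)
    list(context = cc, frames = af$frame, n = nrow(af), H = H,
         dirbin = dirbin, sbin = sbin, posmap = posmap,
         half_time = half_time, half_par = half_par,
         occ = occ_min(rep(TRUE, nrow(af))),
         occ_t1 = occ_min(half_time == 1L), occ_t2 = occ_min(half_time == 2L),
         occ_p1 = occ_min(half_par == 1L), occ_p2 = occ_min(half_par == 2L),
         joint = P)
  })
  names(prep_ctx) <- ctxs
  list(g = g, ctx = prep_ctx, config = config, reference = reference,
       nb_dir = nb_dir)
}

# tuning curve (events/min per bin; NA where occupancy is zero)
dir_curve <- function(counts, occ_min) {
  ifelse(occ_min > 0, counts / occ_min, NA_real_)
}

# Rayleigh vector of a tuning curve on bin centres theta
rayleigh_vector <- function(curve, theta) {
  ok <- !is.na(curve)
  s <- sum(curve[ok])
  if (!any(ok) || s <= 0) return(c(length = NA_real_, angle = NA_real_))
  z <- sum(curve[ok] * exp(1i * theta[ok])) / s
  c(length = Mod(z), angle = Arg(z))
}

# vectorized Rayleigh length over count matrix columns (shared occupancy)
rayleigh_lengths <- function(C, occ_min, theta) {
  ok <- occ_min > 0
  R <- C[ok, , drop = FALSE] / occ_min[ok]
  s <- colSums(R)
  num <- Mod(t(R) %*% exp(1i * theta[ok]))
  ifelse(s > 0, as.numeric(num) / s, NA_real_)
}

dir_bin_centers <- function(nb) (seq_len(nb) - 1) * 2 * pi / nb

# ---- exported surface -----------------------------------------------------

#' Directional tuning curve and Rayleigh vector
#'
#' Event rate per 45 degree bin of the relative running direction (events in
#' bin / time in bin) during running foraging frames of one context, and the
#' Rayleigh vector of the curve: \eqn{|\sum_b r_b e^{i\theta_b}| / \sum_b
#' r_b} with \eqn{\theta_b} the bin centres. Zero-occupancy bins are excluded
#' from the vector sum.
#'
#' @param session A `remap_session`.
#' @param neuron Neuron id.
#' @param context Context label.
#' @param config A [remap_config()].
#' @param reference Optional reference point override.
#' @return Tibble with one row per bin: `bin`, `theta` (bin centre, rad),
#'   `rate`, plus attributes-free columns `L` and `angle` recycled.
#' @export
directional_tuning <- function(session, neuron, context,
                               config = remap_config(), reference = NULL) {
  prep <- directional_prep(session, config, reference = reference)
  cx <- prep$ctx[[context]]
  if (is.null(cx)) stop("no analysis frames in context ", context, call. = FALSE)
  ev <- session$events$frame[session$events$neuron == neuron]
  pos <- cx$posmap[ev + 1L]; pos <- pos[!is.na(pos)]
  counts <- tabulate(cx$dirbin[pos], nbins = prep$nb_dir)
  theta <- dir_bin_centers(prep$nb_dir)
  curve <- dir_curve(counts, cx$occ)
  rv <- rayleigh_vector(curve, theta)
  tibble::tibble(bin = seq_len(prep$nb_dir), theta = wrap_angle(theta),
                 rate = curve, L = rv[["length"]], angle = rv[["angle"]])
}

#' Full directional analysis of a population
#'
#' For each neuron and context: the 8-bin tuning curve and Rayleigh vector;
#' split-half stability of the curve (first/second half and even/odd trials,
#' Pearson over bins, averaged); two circular-shuffle null distributions of
#' the Rayleigh length (event shift, and shift of the direction series
#' relative to the events, both with the >= 1 min offset rule); and the
#' reconstruction analysis: the tuning curve reconstructed under a
#' pure-place assumption \eqn{r'(H) = \sum_{xy} p(x,y,H) r(x,y) / \sum_{xy}
#' p(x,y,H)}, the spatial map reconstructed under a pure-direction
#' assumption \eqn{r'(x,y) = \sum_H p(x,y,H) r(H) / \sum_H p(x,y,H)}, each
#' compared with its observation via
#' \eqn{Error = \langle(obs - rec)^2\rangle / (\max(obs) - \min(obs))}
#' after normalizing both maps to their own peak, and the direction/place
#' index (place-assumption error over direction-assumption error; above 1
#' indicates directional modulation beyond occupancy bias).
#'
#' @param session A `remap_session`.
#' @param neurons Neuron ids (default all).
#' @param n_shuffle Shuffles per null (default from `config`).
#' @param seed Integer seed.
#' @param config A [remap_config()].
#' @param frames Optional precomputed spatial-mode frames table.
#' @param reference Optional reference point override (defaults to the
#'   geometry's reference point).
#' @return Tibble with one row per neuron and context: `neuron`, `context`,
#'   `n_events`, `L`, `angle`, `r_split`, `r_evenodd`, `r_mean`,
#'   `null95_event`, `null95_dir`, `err_place`, `err_dir`, `index`,
#'   `stable`, `significant`, `pass` (all three criteria in this context)
#'   and list-column `curve`.
#' @export
directional_analysis <- function(session, neurons = NULL, n_shuffle = NULL,
                                 seed = NULL, config = remap_config(),
                                 frames = NULL, reference = NULL) {
  n_shuffle <- n_shuffle %||% config$n_shuffle
  dprep <- directional_prep(session, config, frames, reference)
  sprep <- spatial_prep(session, config, frames)
  theta <- dir_bin_centers(dprep$nb_dir)
  if (is.null(neurons)) neurons <- sort(unique(session$events$neuron))
  ev_by <- split(session$events$frame, session$events$neuron)
  margin <- round(config$shuffle_margin * config$frame_rate)
  purrr::map_dfr(seq_along(neurons), function(i) {
    id <- neurons[i]
    ev <- ev_by[[as.character(id)]] %||% integer()
    dplyr::bind_rows(purrr::imap(dprep$ctx, function(cx, label) {
      if (is.null(cx)) return(NULL)
      pos <- cx$posmap[ev + 1L]; pos <- pos[!is.na(pos)]
      counts <- tabulate(cx$dirbin[pos], nbins = dprep$nb_dir)
      curve <- dir_curve(counts, cx$occ)
      rv <- rayleigh_vector(curve, theta)
      # split-half stability of the curve
      cor8 <- function(c1, o1, c2, o2) {
        a <- dir_curve(c1, o1); b <- dir_curve(c2, o2)
        m <- !is.na(a) & !is.na(b)
        if (sum(m) < 2 || stats::sd(a[m]) == 0 || stats::sd(b[m]) == 0)
          NA_real_ else stats::cor(a[m], b[m])
      }
      tab_half <- function(memb) tabulate(cx$dirbin[pos[memb]],
                                          nbins = dprep$nb_dir)
      r_sp <- cor8(tab_half(cx$half_time[pos] == 1L), cx$occ_t1,
                   tab_half(cx$half_time[pos] == 2L), cx$occ_t2)
      r_eo <- cor8(tab_half(cx$half_par[pos] == 1L), cx$occ_p1,
                   tab_half(cx$half_par[pos] == 2L), cx$occ_p2)
      r_mean <- (r_sp + r_eo) / 2
      # dual nulls of the Rayleigh length
      nulls <- if (cx$n > 2 * margin && length(pos)) {
        with_seed(child_seed(seed, i * 4L + match(label, names(dprep$ctx))), {
          offs <- matrix(sample(seq.int(margin, cx$n - margin),
                                2 * n_shuffle, replace = TRUE), ncol = 2)
          Ce <- Cd <- matrix(0L, dprep$nb_dir, n_shuffle)
          for (s in seq_len(n_shuffle)) {
            pe <- ((pos - 1L + offs[s, 1]) %% cx$n) + 1L
            Ce[, s] <- tabulate(cx$dirbin[pe], nbins = dprep$nb_dir)
            # direction-series shift: events sample the rotated H sequence
            pd <- ((pos - 1L + offs[s, 2]) %% cx$n) + 1L
            Cd[, s] <- tabulate(cx$dirbin[pd], nbins = dprep$nb_dir)
          }
          list(ev = rayleigh_lengths(Ce, cx$occ, theta),
               dir = rayleigh_lengths(Cd, cx$occ, theta))
        })
      } else {
        list(ev = NA_real_, dir = NA_real_)
      }
      q <- function(x) if (all(is.na(x))) NA_real_ else
        stats::quantile(x, config$null_quantile, na.rm = TRUE, names = FALSE)
      # reconstruction analysis
      scx <- sprep$ctx[[label]]
      spos <- ctx_positions(scx, ev)
      smap <- half_rate(scx$full, tabulate(scx$bin[spos],
                                           nbins = dprep$g$nbin))
      rec <- reconstruction_errors(smap, curve, cx$joint)
      stable <- !is.na(r_mean) && r_mean > config$stability_floor
      signif <- !is.na(rv[["length"]]) &&
        !is.na(q(nulls$ev)) && !is.na(q(nulls$dir)) &&
        rv[["length"]] > q(nulls$ev) && rv[["length"]] > q(nulls$dir)
      idx_ok <- !is.na(rec["index"]) && rec[["index"]] > 1
      tibble::tibble(
        neuron = id, context = label, n_events = length(pos),
        L = rv[["length"]], angle = rv[["angle"]],
        r_split = r_sp, r_evenodd = r_eo, r_mean = r_mean,
        null95_event = q(nulls$ev), null95_dir = q(nulls$dir),
        err_place = rec[["err_place"]], err_dir = rec[["err_dir"]],
        index = rec[["index"]],
        stable = stable, significant = signif,
        pass = stable && signif && idx_ok,
        curve = list(curve)
      )
    }))
  })
}

# reconstruction errors from the observed spatial map (rate per spatial bin),
# observed tuning curve, and joint occupancy counts P (nbin x ndir)
reconstruction_errors <- function(smap, curve, P) {
  valid_xy <- !is.na(smap)
  valid_h <- !is.na(curve)
  err <- function(obs, rec) {
    m <- !is.na(obs) & !is.na(rec)
    if (!any(m)) return(NA_real_)
    o <- obs[m]; r <- rec[m]
    if (max(o) <= 0) return(NA_real_)
    o <- o / max(o)
    if (max(r) > 0) r <- r / max(r)
    den <- max(o) - min(o)
    if (den == 0) return(NA_real_)
    mean((o - r)^2) / den
  }
  # r'(H): tuning expected from the place map and occupancy alone
  Ph <- P[valid_xy, , drop = FALSE]
  denom_h <- colSums(Ph)
  rec_h <- ifelse(denom_h > 0,
                  as.numeric(t(Ph) %*% smap[valid_xy]) / denom_h, NA_real_)
  # r'(x, y): map expected from the tuning curve and occupancy alone
  Pxy <- P[, valid_h, drop = FALSE]
  denom_xy <- rowSums(Pxy)
  rec_xy <- ifelse(denom_xy > 0,
                   as.numeric(Pxy %*% curve[valid_h]) / denom_xy, NA_real_)
  rec_xy[!valid_xy] <- NA_real_
  c(err_place = err(curve, rec_h),
    err_dir = err(smap, rec_xy),
    index = {
      ep <- err(curve, rec_h); ed <- err(smap, rec_xy)
      if (is.na(ep) || is.na(ed) || ed == 0) NA_real_ else ep / ed
    })
}

#' Classify directionally modulated and conjunctive cells
#'
#' A neuron is a directionally modulated cell (DC) when, in at least one
#' context, its tuning curve is stable (mean split correlation > 0.4), its
#' Rayleigh length exceeds the 95th percentile of both shuffle nulls, and
#' its direction/place index exceeds 1 — and it fired at least 10 events.
#' Conjunctive cells are DCs that are also place cells. For cells tuned in
#' both contexts the wrapped angular difference of the Rayleigh angles is
#' reported.
#'
#' @param dir_results Tibble from [directional_analysis()].
#' @param place_cells Optional tibble with `neuron`, `is_place_cell` (from
#'   [place_cell_analysis()]).
#' @param total_events Optional named vector of session event counts per
#'   neuron; defaults to the per-context maximum of `n_events` in
#'   `dir_results`.
#' @param config A [remap_config()].
#' @return Tibble with one row per neuron: `neuron`, `is_DC`,
#'   `is_conjunctive`, `context_selectivity` (`"context-1-only"`,
#'   `"context-2-only"`, `"both"` or `NA`), `tuning_difference` (rad, only
#'   for both-context cells) and `tuned_angle` (Rayleigh angle of the tuned
#'   context; first context if both).
#' @export
classify_directional_cells <- function(dir_results, place_cells = NULL,
                                       total_events = NULL,
                                       config = remap_config()) {
  ctxs <- unique(dir_results$context)
  out <- dir_results |>
    dplyr::group_by(neuron = .data$neuron) |>
    dplyr::summarise(
      n_total = sum(.data$n_events),
      pass1 = .data$pass[.data$context == ctxs[1]][1],
      pass2 = .data$pass[.data$context == ctxs[2]][1],
      angle1 = .data$angle[.data$context == ctxs[1]][1],
      angle2 = .data$angle[.data$context == ctxs[2]][1],
      .groups = "drop")
  if (!is.null(total_events)) {
    out$n_total <- as.numeric(total_events[as.character(out$neuron)])
  }
  out <- out |>
    dplyr::mutate(
      pass1 = !is.na(.data$pass1) & .data$pass1,
      pass2 = !is.na(.data$pass2) & .data$pass2,
      is_DC = (.data$pass1 | .data$pass2) & .data$n_total >= config$min_events,
      context_selectivity = dplyr::case_when(
        !.data$is_DC ~ NA_character_,
        .data$pass1 & .data$pass2 ~ "both",
        .data$pass1 ~ "context-1-only",
        TRUE ~ "context-2-only"
      ),
      tuning_difference = ifelse(.data$is_DC & .data$pass1 & .data$pass2,
                                 abs(wrap_angle(.data$angle1 - .data$angle2)),
                                 NA_real_),
      tuned_angle = dplyr::case_when(
        !.data$is_DC ~ NA_real_,
        .data$pass1 ~ .data$angle1,
        TRUE ~ .data$angle2
      )
    ) |>
    dplyr::select("neuron", "is_DC", "context_selectivity",
                  "tuning_difference", "tuned_angle")
  if (!is.null(place_cells)) {
    pc <- dplyr::distinct(place_cells, .data$neuron, .data$is_place_cell)
    out <- dplyr::left_join(out, pc, by = "neuron") |>
      dplyr::mutate(is_place_cell = !is.na(.data$is_place_cell) &
                      .data$is_place_cell,
                    is_conjunctive = .data$is_DC & .data$is_place_cell)
  } else {
    out$is_place_cell <- NA
    out$is_conjunctive <- NA
  }
  out
}

#' Landmark tuning composition of directional cells
#'
#' Maps each DC's tuned Rayleigh angle to the nearest wall (45 degree bins
#' centred on the wall normals) and categorizes the wall as `"reward"`,
#' `"light cue"` or `"other"`. Walls that carry both a light cue and a
#' reward are excluded (dropped from both the cell counts and the chance
#' expectation). The chance expectation is the proportion of (non-excluded)
#' walls in each category. For reward-tuned conjunctive cells with
#' segmented fields, the distance from the reward port of the closest field
#' centre is reported.
#'
#' @param classified Tibble from [classify_directional_cells()].
#' @param geometry An [arena_geometry()] object.
#' @param fields Optional tibble from [assign_reward_fields()]; enables the
#'   reward-tuned field-distance output.
#' @return List with `cells` (per-DC wall and category), `composition`
#'   (category counts and chance expectation) and `reward_tuned_distance`
#'   (per reward-tuned conjunctive cell, cm; `NULL` without `fields`).
#' @export
landmark_tuning_summary <- function(classified, geometry, fields = NULL) {
  w <- geometry$walls
  wall_cat <- dplyr::case_when(
    (w$reward_1 | w$reward_2) & (w$lightcue_1 | w$lightcue_2) ~ "excluded",
    w$reward_1 | w$reward_2 ~ "reward",
    w$lightcue_1 | w$lightcue_2 ~ "light cue",
    TRUE ~ "other"
  )
  dcs <- dplyr::filter(classified, .data$is_DC, !is.na(.data$tuned_angle))
  cells <- dcs |>
    dplyr::mutate(wall = angle_to_wall(.data$tuned_angle),
                  category = wall_cat[.data$wall + 1L]) |>
    dplyr::select("neuron", "tuned_angle", "wall", "category")
  lvls <- c("reward", "light cue", "other")
  keep_walls <- wall_cat != "excluded"
  chance <- as.numeric(table(factor(wall_cat[keep_walls], levels = lvls))) /
    sum(keep_walls)
  obs <- cells[cells$category != "excluded", ]
  composition <- tibble::tibble(
    category = lvls,
    n = as.numeric(table(factor(obs$category, levels = lvls))),
    chance = chance
  )
  reward_dist <- NULL
  if (!is.null(fields) && nrow(fields)) {
    rt <- cells$neuron[cells$category == "reward"]
    if (!is.null(classified$is_conjunctive)) {
      conj <- classified$neuron[!is.na(classified$is_conjunctive) &
                                  classified$is_conjunctive]
      rt <- intersect(rt, conj)
    }
    reward_dist <- fields |>
      dplyr::filter(.data$neuron %in% rt) |>
      dplyr::group_by(neuron = .data$neuron) |>
      dplyr::summarise(closest_field_distance = min(.data$reward_distance),
                       .groups = "drop")
  }
  list(cells = cells, composition = composition,
       reward_tuned_distance = reward_dist)
}
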