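# ---- 2D peak detection with prominence -----------------------------------
#
# Topographic prominence by descending-threshold union-find (persistence):
# bins of the (smoothed) map are processed from highest to lowest; a bin with
# no higher processed neighbour founds a new peak component; when two
# components merge, the lower peak's prominence is its height minus the merge
# level. Unmerged peaks (including the global maximum) get height minus the
# map minimum. Plateaus collapse to their earliest-index bin.

find_peaks_2d <- function(rate, g, valid, min_prominence = 1) {
  v <- rate
  v[!valid | is.na(v)] <- -Inf
  ord <- order(-v, seq_along(v))
  ord <- ord[is.finite(v[ord])]
  if (!length(ord)) {
    return(tibble::tibble(bin = integer(), x = numeric(), y = numeric(),
                          height = numeric(), prominence = numeric()))
  }
  parent <- seq_along(v)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  peak_of <- integer(length(v))     # root -> founding peak bin
  prom <- rep(NA_real_, length(v))  # peak bin -> prominence
  processed <- logical(length(v))
  nx <- g$nx
  for (b in ord) {
    ix <- (b - 1L) %% nx + 1L
    iy <- (b - 1L) %/% nx + 1L
    nbr <- integer()
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      jx <- ix + dx; jy <- iy + dy
      if (jx < 1 || jx > nx || jy < 1 || jy > g$ny) next
      j <- jx + (jy - 1L) * nx
      if (processed[j]) nbr <- c(nbr, j)
    }
    processed[b] <- TRUE
    if (!length(nbr)) {
      peak_of[b] <- b
      next
    }
    roots <- unique(vapply(nbr, find, integer(1)))
    # attach b to the component with the highest peak, merge the others
    hts <- v[peak_of[roots]]
    main <- roots[which.max(hts)]
    parent[b] <- main
    for (r in setdiff(roots, main)) {
      pk <- peak_of[r]
      if (is.na(prom[pk])) prom[pk] <- v[pk] - v[b]
      parent[r] <- main
    }
  }
  vmin <- min(v[is.finite(v)])
  pks <- which(peak_of == seq_along(v) & peak_of > 0)
  prom[pks][is.na(prom[pks])] <- v[pks][is.na(prom[pks])] - vmin
  keep <- pks[prom[pks] >= min_prominence]
  tibble::tibble(bin = keep, x = g$centers_x[keep], y = g$centers_y[keep],
                 height = v[keep], prominence = prom[keep])
}

# ---- weighted Gaussian-mixture EM ----------------------------------------
#
# Full-covariance k-component mixture fitted to bin centres weighted by the
# rate surface, components initialized at the detected peaks. Per-observation
# weights enter both the E-step responsibilities aggregation and the M-step
# moments. Covariances are ridge-regularized to the bin scale.

weighted_gmm <- function(xy, w, init_means, max_iter = 200, tol = 1e-8,
                         ridge = 0.25) {
  k <- nrow(init_means)
  n <- nrow(xy)
  mu <- init_means
  sig <- replicate(k, diag(16, 2), simplify = FALSE)
  pi_k <- rep(1 / k, k)
  W <- sum(w)
  dens <- function(mu_j, sig_j) {
    ch <- tryCatch(chol(sig_j), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    z <- forwardsolve(t(ch), t(sweep(xy, 2, mu_j)))
    exp(-0.5 * colSums(z^2)) / (2 * pi * prod(diag(ch)))
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    D <- matrix(0, n, k)
    for (j in seq_len(k)) {
      dj <- dens(mu[j, ], sig[[j]])
      if (is.null(dj)) return(NULL)
      D[, j] <- pi_k[j] * dj
    }
    rs <- rowSums(D)
    if (any(!is.finite(rs)) || all(rs == 0)) return(NULL)
    rs[rs == 0] <- .Machine$double.xmin
    R <- D / rs
    ll <- sum(w * log(rs))
    wr <- R * w
    nk <- colSums(wr)
    if (any(nk < 1e-10)) return(NULL)
    pi_k <- nk / W
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(xy * wr[, j]) / nk[j]
      cx <- sweep(xy, 2, mu[j, ])
      sig[[j]] <- crossprod(cx * sqrt(wr[, j])) / nk[j] + diag(ridge, 2)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sig, pi = pi_k, resp = R)
}

# ---- field segmentation ---------------------------------------------------

#' Segment place fields of pooled rate maps
#'
#' Events of the two contexts are pooled and the full rate map of each place
#' cell is rebuilt; local maxima with at least 1 event/min prominence set the
#' number of fields k; a k-component Gaussian mixture (bins weighted by rate,
#' components initialized at the peaks) is fitted to the rate surface and
#' pixels are assigned to the component of maximal responsibility. Pixels
#' below 20% of their field's peak are removed, and fields with a peak below
#' 1 event/min or fewer than two attributed events are discarded. If the EM
#' fit degenerates, pixels fall back to nearest-peak assignment (logged via a
#' message).
#'
#' @param session A `remap_session`.
#' @param neurons Neuron ids to segment (default all; typically the place
#'   cells).
#' @param config A [remap_config()].
#' @param overrides Optional declarative override list (see
#'   [apply_field_overrides()]), mirroring a manual curation step.
#' @param frames Optional precomputed spatial-mode frames table.
#' @return Tibble with one row per field: `neuron`, `field`, `center_x`,
#'   `center_y` (component mean, cm), `size` (cm^2), `peak_rate`,
#'   `mean_rate` (events/min over member pixels of the pooled map),
#'   `n_pixels`, `n_events` and list-column `pixels` (bin indices).
#' @export
segment_place_fields <- function(session, neurons = NULL,
                                 config = remap_config(), overrides = NULL,
                                 frames = NULL) {
  prep <- spatial_prep(session, config, frames)
  pl <- pooled_prep(prep)
  g <- prep$g
  if (is.null(neurons)) neurons <- sort(unique(session$events$neuron))
  ev_by <- split(session$events$frame, session$events$neuron)
  out <- purrr::map_dfr(neurons, function(id) {
    ev <- ev_by[[as.character(id)]] %||% integer()
    pos <- ctx_positions(pl, ev)
    counts <- tabulate(pl$bin[pos], nbins = g$nbin)
    rate <- half_rate(pl$full, counts)
    pks <- find_peaks_2d(rate, g, pl$full$valid, config$peak_prominence)
    if (!nrow(pks)) return(NULL)
    vb <- which(pl$full$valid & !is.na(rate) & rate > 0)
    xy <- cbind(g$centers_x[vb], g$centers_y[vb])
    w <- rate[vb]
    assign <- NULL
    if (nrow(pks) == 1) {
      assign <- rep(1L, length(vb))
      centers <- cbind(sum(xy[, 1] * w) / sum(w), sum(xy[, 2] * w) / sum(w))
    } else {
      fit <- weighted_gmm(xy, w, as.matrix(pks[, c("x", "y")]))
      if (is.null(fit)) {
        message("GMM degenerate for neuron ", id,
                "; falling back to nearest-peak assignment")
        d <- outer(xy[, 1], pks$x, "-")^2 + outer(xy[, 2], pks$y, "-")^2
        assign <- max.col(-d)
        centers <- as.matrix(pks[, c("x", "y")])
      } else {
        assign <- max.col(fit$resp)
        centers <- fit$mu
      }
    }
    fields <- purrr::map_dfr(seq_len(nrow(pks)), function(j) {
      memb <- vb[assign == j]
      if (!length(memb)) return(NULL)
      pk <- max(rate[memb])
      memb <- memb[rate[memb] >= config$field_cutoff * pk]
      if (!length(memb)) return(NULL)
      n_ev <- sum(counts[memb])
      tibble::tibble(neuron = id, field = j,
                     center_x = centers[j, 1], center_y = centers[j, 2],
                     size = length(memb) * g$bin^2,
                     peak_rate = pk,
                     mean_rate = mean(rate[memb]),
                     n_pixels = length(memb), n_events = n_ev,
                     pixels = list(memb))
    })
    if (is.null(fields) || !nrow(fields)) return(NULL)
    dplyr::filter(fields, .data$peak_rate >= config$peak_prominence,
                  .data$n_events >= config$min_field_events)
  })
  if (!is.null(out) && nrow(out) && !is.null(overrides)) {
    out <- apply_field_overrides(out, overrides)
  }
  if (is.null(out)) out <- tibble::tibble()
  out
}

#' Apply declarative field overrides
#'
#' Replaces the manual GUI readjustment of field boundaries with an
#' auditable, reproducible override list: `drop` (list of
#' `list(neuron=, field=)`) removes fields and `merge` (list of
#' `list(neuron=, fields=)`) merges a neuron's fields into one (pixels
#' unioned, parameters recomputed from the merged pixel set using the
#' stored per-pixel quantities).
#'
#' @param fields Tibble from [segment_place_fields()].
#' @param overrides List with optional elements `drop` and `merge`.
#' @return The modified fields tibble.
#' @export
apply_field_overrides <- function(fields, overrides) {
  for (d in overrides$drop %||% list()) {
    fields <- dplyr::filter(fields, !(.data$neuron == d$neuron &
                                        .data$field == d$field))
  }
  for (m in overrides$merge %||% list()) {
    sel <- fields$neuron == m$neuron & fields$field %in% m$fields
    if (sum(sel) < 2) next
    rows <- fields[sel, ]
    merged <- rows[1, ]
    merged$pixels <- list(sort(unique(unlist(rows$pixels))))
    merged$n_pixels <- length(merged$pixels[[1]])
    merged$size <- sum(rows$size)
    merged$peak_rate <- max(rows$peak_rate)
    merged$mean_rate <- sum(rows$mean_rate * rows$n_pixels) / sum(rows$n_pixels)
    merged$n_events <- sum(rows$n_events)
    merged$center_x <- sum(rows$center_x * rows$n_pixels) / sum(rows$n_pixels)
    merged$center_y <- sum(rows$center_y * rows$n_pixels) / sum(rows$n_pixels)
    fields <- dplyr::bind_rows(fields[!sel, ], merged) |>
      dplyr::arrange(.data$neuron, .data$field)
  }
  fields
}

#' Rate overlap score
#'
#' \deqn{RateOverlap = 1 - |rate_1 - rate_2| / (rate_1 + rate_2)}
#' 1 means identical rates in the two contexts, 0 complete rate remapping.
#' Undefined (NA) when both rates are zero.
#'
#' @param rate1,rate2 Nonnegative mean field rates (events/min).
#' @return Numeric in `[0, 1]`.
#' @examples
#' rate_overlap(3, 1) # 0.5
#' @export
rate_overlap <- function(rate1, rate2) {
  s <- rate1 + rate2
  ifelse(s > 0, 1 - abs(rate1 - rate2) / s, NA_real_)
}

#' Per-field context rates and rate overlap
#'
#' Computes the mean rate of each field's member pixels in the two context
#' maps and the rate overlap score between them. Fields with zero summed
#' rate are excluded (overlap `NA`).
#'
#' @param fields Tibble from [segment_place_fields()].
#' @param maps Tibble from [context_rate_maps()] with both contexts.
#' @return `fields` with added columns `rate1`, `rate2`, `overlap`.
#' @export
field_rate_overlap <- function(fields, maps) {
  ctxs <- setdiff(unique(maps$context), "pooled")
  stopifnot(length(ctxs) == 2)
  if (!nrow(fields)) return(fields)
  get_rate <- function(id, pix, cc) {
    m <- maps[maps$neuron == id & maps$context == cc, ]
    r <- m$rate[pix]
    r <- r[!is.na(r)]
    if (!length(r)) NA_real_ else mean(r)
  }
  fields |>
    dplyr::mutate(
      rate1 = purrr::map2_dbl(.data$neuron, .data$pixels, get_rate, ctxs[1]),
      rate2 = purrr::map2_dbl(.data$neuron, .data$pixels, get_rate, ctxs[2]),
      overlap = rate_overlap(.data$rate1, .data$rate2)
    )
}

#' Classify fields by distance to reward
#'
#' Euclidean distance from the field centre to the nearest rewarded port
#' (the closer of the two in the discrimination paradigm). Fields within
#' 10 cm are reward fields; other fields fall into 5 cm distance increments.
#'
#' @param fields Tibble with `center_x`, `center_y`.
#' @param geometry An [arena_geometry()] object.
#' @param config A [remap_config()].
#' @return `fields` with added columns `reward_distance` (cm),
#'   `reward_index` (1 or 2: which context's port is nearest; in
#'   generalization always 1), `is_reward_field` and `distance_class`
#'   (`"reward"` or e.g. `"10-15"`).
#' @export
assign_reward_fields <- function(fields, geometry, config = remap_config()) {
  ports <- reward_ports(geometry)
  if (!nrow(fields)) return(fields)
  d <- sapply(seq_len(nrow(ports)), function(i) {
    sqrt((fields$center_x - ports$x[i])^2 + (fields$center_y - ports$y[i])^2)
  })
  d <- matrix(d, nrow = nrow(fields))
  nearest <- max.col(-d, ties.method = "first")
  dist <- d[cbind(seq_len(nrow(fields)), nearest)]
  lo <- config$reward_radius +
    floor((dist - config$reward_radius) / config$distance_bin) *
    config$distance_bin
  fields |>
    dplyr::mutate(
      reward_distance = dist,
      reward_index = as.integer(nearest),
      is_reward_field = dist <= config$reward_radius,
      distance_class = ifelse(.data$is_reward_field, "reward",
                              sprintf("%d-%d", as.integer(lo),
                                      as.integer(lo + config$distance_bin)))
    )
}

#' Firing preference of reward fields
#'
#' \deqn{FP = \frac{rate_1 - rate_2}{rate_1 + rate_2} \cdot (-1)^{k+1}}
#' where k indexes the reward location hosting the field (k = 1: the port
#' rewarded in the first context). Computed on maps rebuilt from correct
#' non-cued trials only. Fields are `"match"` if FP > 0.33, `"mismatch"` if
#' FP < -0.33, else `"neutral"`.
#'
#' @param fields Tibble with `reward_index` and `is_reward_field` (from
#'   [assign_reward_fields()]).
#' @param maps Context maps restricted to correct non-cued trials (see
#'   [context_rate_maps()] with filtered frames).
#' @param config A [remap_config()].
#' @return Reward fields with added `rate1c`, `rate2c` (correct-trial
#'   rates), `preference` and `category`; fields with zero summed rate are
#'   dropped.
#' @export
classify_field_preference <- function(fields, maps, config = remap_config()) {
  rf <- dplyr::filter(fields, .data$is_reward_field)
  if (!nrow(rf)) return(rf)
  rf <- field_rate_overlap(rf, maps) |>
    dplyr::rename(rate1c = "rate1", rate2c = "rate2") |>
    dplyr::select(-"overlap")
  rf |>
    dplyr::mutate(
      preference = (.data$rate1c - .data$rate2c) /
        (.data$rate1c + .data$rate2c) * (-1)^(.data$reward_index + 1),
      category = dplyr::case_when(
        .data$preference > config$preference_cutoff ~ "match",
        .data$preference < -config$preference_cutoff ~ "mismatch",
        TRUE ~ "neutral"
      )
    ) |>
    dplyr::filter(is.finite(.data$preference))
}

#' Histogram of field counts by reward-distance class
#'
#' @param fields Tibble from [assign_reward_fields()].
#' @param paradigm Paradigm label attached to the output.
#' @return Tibble with `paradigm`, `distance_class` (ordered: reward, then
#'   increasing 5 cm bins) and `n`. In the discrimination paradigm, classes
#'   beyond 25 cm trigger a warning (with two rewarded locations, such
#'   distances are only reachable in a narrow band of the arena).
#' @export
field_distance_histogram <- function(fields,
                                     paradigm = c("discrimination",
                                                  "generalization")) {
  paradigm <- match.arg(paradigm)
  if (!nrow(fields)) {
    return(tibble::tibble(paradigm = character(), distance_class = character(),
                          n = integer()))
  }
  out <- fields |>
    dplyr::count(distance_class = .data$distance_class) |>
    dplyr::mutate(paradigm = paradigm, .before = 1)
  lo <- suppressWarnings(as.numeric(sub("-.*", "", out$distance_class)))
  out <- out[order(ifelse(out$distance_class == "reward", -1, lo)), ]
  if (paradigm == "discrimination" && any(lo >= 25, na.rm = TRUE)) {
    warning("discrimination fields beyond 25 cm from both rewards", call. = FALSE)
  }
  out
}
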