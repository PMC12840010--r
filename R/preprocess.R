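#' Label calcium-trace baseline stability
#'
#' Segments a \eqn{\Delta F/F_0} trace into non-overlapping one-minute
#' sections and takes the valley (minimum) of each. A trace is labelled
#' unstable when at least `qc_minutes` (default 5) section valleys exceed the
#' `qc_valley` threshold (default 0.1 \eqn{\Delta F/F_0}); unstable traces
#' are excluded from all downstream analyses. A trace shorter than one
#' section is labelled stable by vacuity, with a warning.
#'
#' @param trace Data frame with columns `neuron` (optional) and `dff`, or a
#'   numeric vector for a single trace.
#' @param config A [remap_config()] (supplies `qc_valley`, `qc_minutes`,
#'   `frame_rate`).
#' @return Tibble with one row per neuron: `neuron`, `n_bad_sections`,
#'   `stability` (`"stable"` or `"unstable"`).
#' @examples
#' label_trace_stability(rep(0.2, 20 * 60 * 6)) # 6 min above threshold
#' @export
label_trace_stability <- function(trace, config = remap_config()) {
  if (is.numeric(trace)) trace <- tibble::tibble(neuron = 1L, dff = trace)
  if (!"neuron" %in% names(trace)) trace$neuron <- 1L
  sec_len <- round(60 * config$frame_rate)
  trace |>
    dplyr::group_by(neuron = .data$neuron) |>
    dplyr::summarise(n_bad_sections = {
      x <- .data$dff
      n_sec <- length(x) %/% sec_len
      if (n_sec == 0) {
        warning("trace shorter than one section; labelled stable by vacuity",
                call. = FALSE)
        0L
      } else {
        valleys <- vapply(seq_len(n_sec), function(s) {
          min(x[((s - 1) * sec_len + 1):(s * sec_len)])
        }, numeric(1))
        sum(valleys > config$qc_valley)
      }
    }, .groups = "drop") |>
    dplyr::mutate(stability = ifelse(.data$n_bad_sections >= config$qc_minutes,
                                     "unstable", "stable"))
}

#' Detect calcium events as peaks of a deconvolved signal
#'
#' Local maxima whose prominence (height above the higher of the two
#' flanking minima separating the peak from larger neighbours) reaches
#' `min_prominence`. Plateau peaks collapse to their earliest frame.
#'
#' @param deconv Numeric deconvolved series, or data frame with columns
#'   `neuron` (optional), `frame` and `deconv`.
#' @param min_prominence Minimum peak prominence (default 0.1).
#' @return Tibble with columns `neuron` and `frame` (0-based event frames).
#' @export
detect_events <- function(deconv, min_prominence = 0.1) {
  if (is.numeric(deconv)) {
    deconv <- tibble::tibble(neuron = 1L, frame = seq_along(deconv) - 1L,
                             deconv = deconv)
  }
  if (!"neuron" %in% names(deconv)) deconv$neuron <- 1L
  deconv |>
    dplyr::group_by(neuron = .data$neuron) |>
    dplyr::reframe(frame = {
      x <- .data$deconv
      stopifnot(all(is.finite(x)))
      .data$frame[peaks_1d(x, min_prominence)]
    }) |>
    dplyr::arrange(.data$neuron, .data$frame) |>
    tibble::as_tibble()
}

# indices of local maxima of x with prominence >= prom; plateaus collapse to
# their first index
peaks_1d <- function(x, prom) {
  n <- length(x)
  if (n < 1) return(integer())
  # candidate peaks: strictly greater than previous distinct value and >= next
  keep <- logical(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L  # plateau [i, j]
    left_ok <- i == 1L || x[i - 1L] < x[i]
    right_ok <- j == n || x[j + 1L] < x[i]
    if (left_ok && right_ok && (i > 1L || j < n)) keep[i] <- TRUE
    i <- j + 1L
  }
  cand <- which(keep)
  if (!length(cand)) return(integer())
  ok <- vapply(cand, function(p) {
    h <- x[p]
    # walk left until a higher value; track the minimum on the way
    lmin <- h
    k <- p
    while (k > 1L) {
      k <- k - 1L
      if (x[k] > h) break
      lmin <- min(lmin, x[k])
    }
    if (k == 1L && x[k] <= h) lmin <- min(lmin, x[k])
    rmin <- h
    k <- p
    while (k < n) {
      k <- k + 1L
      if (x[k] > h) break
      rmin <- min(rmin, x[k])
    }
    if (k == n && x[k] <= h) rmin <- min(rmin, x[k])
    (h - max(lmin, rmin)) >= prom
  }, logical(1))
  cand[ok]
}

#' Compute running speed from body tracking
#'
#' Body position is smoothed with a 167 ms wide centred moving average
#' (3 frames at 20 Hz) and speed is the frame-to-frame displacement times
#' the frame rate; the last value is replicated to preserve length.
#'
#' @param tracking Data frame with columns `body_x`, `body_y` (and
#'   optionally `frame`).
#' @param config A [remap_config()].
#' @return Tibble with columns `frame` and `speed` (cm/s).
#' @export
compute_speed <- function(tracking, config = remap_config()) {
  n <- nrow(tracking)
  if (n < 2) stop("need at least 2 frames to compute speed", call. = FALSE)
  w <- smooth_window(config)
  sx <- moving_average(tracking$body_x, w)
  sy <- moving_average(tracking$body_y, w)
  sp <- sqrt(diff(sx)^2 + diff(sy)^2) * config$frame_rate
  tibble::tibble(frame = col_or(tracking, "frame", seq_len(n) - 1L),
                 speed = c(sp, sp[length(sp)]))
}

# moving-average width in frames: nearest odd frame count to the configured
# window (167 ms at 20 Hz -> 3 frames)
smooth_window <- function(config) {
  w <- round(config$speed_smooth_ms / 1000 * config$frame_rate)
  max(1L, w + (w %% 2 == 0))
}

# centred moving average, shrinking the window at the edges
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  half <- (w - 1) / 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Segment a session into analysis frames
#'
#' Builds the per-frame masks used downstream. The foraging phase of a trial
#' runs from the first frame with speed above the locomotion threshold
#' (2 cm/s) after trial start up to (excluding) the trigger frame. Spatial
#' analyses (`mode = "spatial"`) additionally require locomotion on every
#' frame; decoding (`mode = "decoding"`) keeps resting frames within the
#' foraging phase. Inter-trial-interval and retrieval-phase frames are never
#' analysis frames.
#'
#' @param session A `remap_session` (or a list with `trials` and `n_frames`).
#' @param speed Tibble from [compute_speed()] on the same clock.
#' @param mode `"spatial"` or `"decoding"`.
#' @param config A [remap_config()].
#' @return Tibble with one row per frame inside a trial: `frame`, `trial`,
#'   `context`, `cued`, `outcome`, `is_running`, `is_rest`, `is_foraging`,
#'   and `analysis` (the mode-specific mask).
#' @export
extract_analysis_frames <- function(session, speed = NULL,
                                    mode = c("spatial", "decoding"),
                                    config = remap_config()) {
  mode <- match.arg(mode)
  if (is.null(speed)) speed <- compute_speed(session$tracking, config)
  trials <- session$trials
  stopifnot(nrow(trials) > 0)
  sp <- speed$speed
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    fr <- trials$start_frame[i]:trials$end_frame[i]
    fr <- fr[fr < session$n_frames]
    run <- sp[fr + 1L] > config$run_speed
    pre_trigger <- fr < trials$trigger_frame[i]
    loco <- which(run & pre_trigger)
    forage <- rep(FALSE, length(fr))
    if (length(loco)) forage <- seq_along(fr) >= loco[1] & pre_trigger
    tibble::tibble(frame = as.integer(fr), trial = trials$trial[i],
                   context = trials$context[i], cued = trials$cued[i],
                   outcome = trials$outcome[i],
                   is_running = run, is_rest = !run, is_foraging = forage)
  })
  out <- dplyr::bind_rows(rows)
  out$analysis <- if (mode == "spatial") {
    out$is_foraging & out$is_running
  } else {
    out$is_foraging
  }
  out
}
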