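#' Simulate a complete recording session
#'
#' Convenience wrapper chaining [simulate_trajectory()],
#' [simulate_trial_sequence()] and [simulate_event_trains()] into a session
#' container holding tracking, trials, events and the planted ground truth.
#' Child seeds for the three stages are derived deterministically from
#' `seed`, so identical arguments reproduce the session exactly.
#'
#' @param truth A [make_ground_truth()] tibble (its geometry must match
#'   `geometry`).
#' @param geometry An [arena_geometry()] object.
#' @param duration Session duration in seconds (default 2400, i.e. 40 min).
#' @param n_trials Trials requested (default 80).
#' @param seed Integer master seed.
#' @param policy,p_correct,p_timeout Agent policy arguments passed to
#'   [simulate_trial_sequence()].
#' @param motion Motion parameters passed to [simulate_trajectory()].
#' @param frame_rate Frames per second (default 20, the master clock; real
#'   tracking recorded on a different clock must be resampled to the imaging
#'   clock before analysis).
#' @return An object of class `remap_session`: a list with elements
#'   `geometry`, `frame_rate`, `paradigm`, `tracking`, `trials`, `events`,
#'   `truth`, `n_frames`.
#' @examples
#' geom <- arena_geometry()
#' tr <- make_ground_truth(geom, n_place = 2, n_background = 1, seed = 1)
#' ses <- simulate_session(tr, geom, duration = 120, n_trials = 4, seed = 1)
#' ses$trials
#' @export
simulate_session <- function(truth, geometry, duration = 2400, n_trials = 80,
                             seed = NULL, policy = "perfect",
                             p_correct = 0.8, p_timeout = 0.02,
                             motion = list(), frame_rate = 20) {
  tracking <- simulate_trajectory(geometry, duration, seed = child_seed(seed, 1),
                                  motion = motion, frame_rate = frame_rate)
  trials <- simulate_trial_sequence(geometry, tracking, n_trials,
                                    seed = child_seed(seed, 2), policy = policy,
                                    p_correct = p_correct, p_timeout = p_timeout,
                                    frame_rate = frame_rate)
  events <- simulate_event_trains(truth, geometry, tracking, trials,
                                  seed = child_seed(seed, 3),
                                  frame_rate = frame_rate)
  new_session(geometry, tracking, trials, events, truth, frame_rate)
}

new_session <- function(geometry, tracking, trials, events, truth = NULL,
                        frame_rate = 20) {
  structure(
    list(geometry = geometry, frame_rate = frame_rate,
         paradigm = geometry$paradigm, tracking = tracking, trials = trials,
         events = events, truth = truth, n_frames = nrow(tracking)),
    class = "remap_session"
  )
}

#' @export
print.remap_session <- function(x, ...) {
  cat(sprintf(paste0("<remap_session> %s paradigm, %.1f min at %d Hz, ",
                     "%d trials, %d neurons, %d events\n"),
              x$paradigm, x$n_frames / x$frame_rate / 60, x$frame_rate,
              nrow(x$trials), length(unique(x$events$neuron)),
              nrow(x$events)))
  invisible(x)
}

#' Write a session to a plain-text dataset directory
#'
#' Layout: `tracking.csv`, `trials.csv`, one `events/<neuron>.csv` per
#' neuron, `geometry.json`, `config.json` and (if ground truth is present)
#' `truth.json`. The layout round-trips losslessly through
#' [read_dataset()].
#'
#' @param session A `remap_session`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(session, dir) {
  stopifnot(inherits(session, "remap_session"))
  dir.create(file.path(dir, "events"), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(session$tracking, file.path(dir, "tracking.csv"))
  readr::write_csv(session$trials, file.path(dir, "trials.csv"))
  for (id in sort(unique(session$events$neuron))) {
    readr::write_csv(
      dplyr::filter(session$events, .data$neuron == id)["frame"],
      file.path(dir, "events", sprintf("%d.csv", id))
    )
  }
  g <- session$geometry
  jsonlite::write_json(
    list(radius = g$radius, paradigm = g$paradigm, contexts = g$contexts,
         reference = g$reference,
         lightcue_walls = stats::setNames(
           list(g$walls$wall[g$walls$lightcue_1], g$walls$wall[g$walls$lightcue_2]),
           g$contexts),
         reward_walls = stats::setNames(
           as.list(c(g$walls$wall[g$walls$reward_1][1],
                     g$walls$wall[g$walls$reward_2][1])),
           g$contexts)),
    file.path(dir, "geometry.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(list(frame_rate = session$frame_rate,
                            n_frames = session$n_frames),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(session$truth)) {
    tr <- as.data.frame(tidyr::unnest(
      session$truth, "fields", keep_empty = TRUE))
    jsonlite::write_json(tr, file.path(dir, "truth.json"), digits = NA)
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `remap_session`.
#' @export
read_dataset <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  gj <- jsonlite::read_json(file.path(dir, "geometry.json"), simplifyVector = TRUE)
  geometry <- arena_geometry(
    radius = gj$radius, paradigm = gj$paradigm,
    lightcue_walls = lapply(gj$lightcue_walls, as.integer),
    reward_walls = vapply(gj$reward_walls, as.integer, integer(1)),
    reference = gj$reference
  )
  tracking <- readr::read_csv(file.path(dir, "tracking.csv"),
                              show_col_types = FALSE)
  trials <- readr::read_csv(
    file.path(dir, "trials.csv"), show_col_types = FALSE,
    col_types = readr::cols(context = readr::col_character(),
                            outcome = readr::col_character(),
                            cued = readr::col_logical(),
                            .default = readr::col_guess())
  )
  for (cc in c("trial", "start_frame", "trigger_frame", "end_frame",
               "visited_port")) {
    if (cc %in% names(trials)) trials[[cc]] <- as.integer(trials[[cc]])
  }
  ev_files <- list.files(file.path(dir, "events"), pattern = "\\.csv$",
                         full.names = TRUE)
  ids <- as.integer(sub("\\.csv$", "", basename(ev_files)))
  events <- dplyr::bind_rows(purrr::map2(ev_files, ids, function(f, id) {
    fr <- readr::read_csv(f, show_col_types = FALSE)
    tibble::tibble(neuron = id, frame = as.integer(fr$frame))
  }))
  if (!nrow(events)) {
    events <- tibble::tibble(neuron = integer(), frame = integer())
  }
  events <- dplyr::arrange(events, .data$neuron, .data$frame)
  truth_file <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_file)) {
    flat <- jsonlite::read_json(truth_file, simplifyVector = TRUE)
    renest_truth(tibble::as_tibble(flat))
  }
  new_session(geometry, tracking, trials, events, truth,
              frame_rate = cfg$frame_rate)
}

# rebuild the nested truth tibble from its flat (unnested) serialization
renest_truth <- function(flat) {
  field_cols <- c("center_x", "center_y", "center_x2", "center_y2",
                  "width", "amp", "gain_1", "gain_2")
  out <- flat |>
    dplyr::group_by(.data$neuron, .data$cell_class, .data$baseline,
                    .data$remapping, .data$dir_mu, .data$dir_kappa,
                    .data$dir_depth, .data$dir_context) |>
    tidyr::nest(fields = dplyr::all_of(field_cols)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$neuron)
  out$fields <- lapply(out$fields, function(f) {
    f <- tibble::as_tibble(f)
    f[stats::complete.cases(f[, c("center_x", "width")]), ]
  })
  cols <- c("neuron", "cell_class", "baseline", "remapping", "fields",
            "dir_mu", "dir_kappa", "dir_depth", "dir_context")
  out <- out[, cols]
  class(out) <- c("remap_truth", class(out))
  out
}
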