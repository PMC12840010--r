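#' Simulate a pseudo-randomized trial schedule over a trajectory
#'
#' Walks through a tracking series and lays out trials of the two-context
#' task: each trial starts in one context (context identities balanced within
#' one trial and intermingled), a hidden 7x7 cm trigger zone is placed at a
#' random location, and the foraging phase ends when the body first enters
#' the zone at least 10 s after trial start. The reward-retrieval phase is
#' resolved by a configurable agent policy; timed-out trials last 60 s after
#' the tone. Consecutive trials are separated by a 3 s inter-trial interval.
#'
#' @param geometry An [arena_geometry()] object.
#' @param tracking Tracking tibble from [simulate_trajectory()].
#' @param n_trials Number of trials requested; if the trajectory is exhausted
#'   first, a truncated schedule is returned with a warning.
#' @param seed Integer seed.
#' @param policy Agent policy resolving the retrieval phase: `"perfect"`
#'   (always visits the correct port), `"random"` (uniform over the 8 ports),
#'   or `"biased"` (correct with probability `p_correct`, otherwise uniform
#'   over the other ports).
#' @param p_correct Hit probability of the biased agent (default 0.8).
#' @param p_timeout Probability that the agent visits no port (default 0.02;
#'   the trial then ends 60 s after the tone).
#' @param cued_block Two integers: trials come in repeating blocks of
#'   `cued_block[1]` cued then `cued_block[2]` non-cued trials (default
#'   `c(8, 24)`, the training-phase structure).
#' @param frame_rate Frames per second.
#' @return Tibble with one row per trial: `trial`, `context`, `cued`,
#'   `start_frame`, `trigger_frame`, `end_frame`, `outcome` (`correct`,
#'   `incorrect` or `timeout`), `visited_port` (wall id, `NA` on timeout) and
#'   the trigger-zone centre `zone_x`, `zone_y`.
#' @export
simulate_trial_sequence <- function(geometry, tracking, n_trials, seed = NULL,
                                    policy = c("perfect", "random", "biased"),
                                    p_correct = 0.8, p_timeout = 0.02,
                                    cued_block = c(8, 24), frame_rate = 20) {
  stopifnot(inherits(geometry, "remap_arena"), n_trials >= 1)
  policy <- match.arg(policy)
  n_frames <- nrow(tracking)
  contexts <- geometry$contexts
  rw <- stats::setNames(
    c(geometry$walls$wall[geometry$walls$reward_1],
      geometry$walls$wall[geometry$walls$reward_2]),
    contexts
  )
  zone_half <- 3.5
  min_forage <- round(10 * frame_rate)
  iti <- round(3 * frame_rate)
  timeout_len <- round(60 * frame_rate)

  with_seed(seed, {
    # balanced, intermingled context labels: shuffled pairs
    ctx_seq <- unlist(lapply(seq_len(ceiling(n_trials / 2)),
                             function(i) sample(contexts)))[seq_len(n_trials)]
    block <- sum(cued_block)
    cued_seq <- ((seq_len(n_trials) - 1) %% block) < cued_block[1]

    rows <- vector("list", n_trials)
    cur <- 1L
    for (tr in seq_len(n_trials)) {
      if (cur + min_forage >= n_frames) break
      # trigger zone fully inside the octagon
      repeat {
        zc <- stats::runif(2, -geometry$radius, geometry$radius)
        corners <- cbind(zc[1] + c(-1, -1, 1, 1) * zone_half,
                         zc[2] + c(-1, 1, -1, 1) * zone_half)
        if (all(in_arena(corners, geometry))) break
      }
      eligible <- seq.int(cur + min_forage, n_frames)
      in_zone <- abs(tracking$body_x[eligible] - zc[1]) <= zone_half &
        abs(tracking$body_y[eligible] - zc[2]) <= zone_half
      hit <- which(in_zone)
      if (!length(hit)) break
      trig <- eligible[hit[1]]
      ctx <- ctx_seq[tr]
      if (stats::runif(1) < p_timeout && policy != "perfect") {
        visited <- NA_integer_
        outcome <- "timeout"
        end <- trig + timeout_len
      } else {
        visited <- switch(policy,
          perfect = rw[[ctx]],
          random = sample(0:7, 1),
          biased = if (stats::runif(1) < p_correct) rw[[ctx]] else
            sample(setdiff(0:7, rw[[ctx]]), 1)
        )
        outcome <- if (visited == rw[[ctx]]) "correct" else "incorrect"
        end <- trig + round(stats::runif(1, 3, 10) * frame_rate)
      }
      end <- min(end, n_frames - 1L)
      rows[[tr]] <- tibble::tibble(
        trial = tr, context = ctx, cued = cued_seq[tr],
        start_frame = cur - 1L, trigger_frame = as.integer(trig - 1L),
        end_frame = as.integer(end - 1L),
        outcome = outcome, visited_port = as.integer(visited),
        zone_x = zc[1], zone_y = zc[2]
      )
      cur <- as.integer(end + iti + 1L)
      if (cur >= n_frames) { tr <- tr + 1L; break }
    }
    out <- dplyr::bind_rows(rows)
    if (nrow(out) < n_trials) {
      warning(sprintf("trajectory exhausted after %d of %d trials",
                      nrow(out), n_trials), call. = FALSE)
    }
    out
  })
}
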