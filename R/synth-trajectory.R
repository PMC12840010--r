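#' Simulate a foraging trajectory in the octagonal arena
#'
#' Generates head and body tracking at the master frame rate with a
#' waypoint-seeking correlated random walk: the animal runs toward a sequence
#' of random goals inside the arena with autocorrelated speed and heading
#' noise, interleaved with brief resting bouts (speed < 2 cm/s). The walk is
#' confined to the octagon and, over a 40-minute default session, covers more
#' than 90% of the 2x2 cm bins.
#'
#' @param geometry An [arena_geometry()] object.
#' @param duration Session duration in seconds (0 gives an empty series).
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   series exactly.
#' @param motion Named list of motion parameters; any subset of `mean_speed`
#'   (cm/s, default 9), `speed_sd` (cm/s, 3), `speed_ac` (per-frame speed
#'   autocorrelation, 0.90), `turn_sd` (rad/frame heading noise, 0.25),
#'   `pause_prob` (per-frame probability of starting a rest bout, 0.004),
#'   `pause_resume` (per-frame probability of ending one, 0.035),
#'   `wall_bias` (0..1, fraction of waypoints drawn near the perimeter, 0.25),
#'   `head_offset` (cm from body to head along heading, 1.5).
#' @param frame_rate Frames per second (default 20).
#' @return Tibble with columns `frame` (0-based), `time` (s), `head_x`,
#'   `head_y`, `body_x`, `body_y` (cm).
#' @examples
#' geom <- arena_geometry()
#' trk <- simulate_trajectory(geom, duration = 60, seed = 1)
#' range(trk$body_x)
#' @export
simulate_trajectory <- function(geometry, duration, seed = NULL,
                                motion = list(), frame_rate = 20) {
  stopifnot(inherits(geometry, "remap_arena"))
  if (!is.numeric(duration) || duration < 0) {
    stop("`duration` must be a nonnegative number of seconds", call. = FALSE)
  }
  m <- utils::modifyList(
    list(mean_speed = 9, speed_sd = 3, speed_ac = 0.90, turn_sd = 0.25,
         pause_prob = 0.004, pause_resume = 0.035, wall_bias = 0.25,
         head_offset = 1.5),
    motion
  )
  n <- floor(duration * frame_rate)
  empty <- tibble::tibble(frame = integer(), time = numeric(),
                          head_x = numeric(), head_y = numeric(),
                          body_x = numeric(), body_y = numeric())
  if (n == 0) return(empty)
  dt <- 1 / frame_rate
  apo <- geometry$apothem
  wall_ang <- geometry$walls$normal_angle

  inside <- function(p, slack = 0.3) {
    all(p[1] * cos(wall_ang) + p[2] * sin(wall_ang) <= apo - slack)
  }
  clamp_in <- function(p, slack = 0.3) {
    proj <- p[1] * cos(wall_ang) + p[2] * sin(wall_ang)
    over <- max(proj) - (apo - slack)
    if (over > 0) p * (apo - slack) / (max(proj) + 1e-12) else p
  }

  with_seed(seed, {
    draw_waypoint <- function() {
      repeat {
        if (stats::runif(1) < m$wall_bias) {
          # point near the perimeter: random wall, near its midpoint band
          k <- sample(0:7, 1)
          d <- stats::runif(1, 0.6, 0.95) * apo
          off <- stats::runif(1, -0.3, 0.3) * apo
          a <- k * pi / 4
          p <- c(d * cos(a) - off * sin(a), d * sin(a) + off * cos(a))
        } else {
          p <- stats::runif(2, -geometry$radius, geometry$radius)
        }
        if (inside(p, slack = 1)) return(p)
      }
    }
    bx <- by <- hx <- hy <- numeric(n)
    p <- c(0, 0)
    theta <- stats::runif(1, -pi, pi)
    v <- m$mean_speed
    wp <- draw_waypoint()
    resting <- FALSE
    for (i in seq_len(n)) {
      if (resting) {
        if (stats::runif(1) < m$pause_resume) resting <- FALSE
      } else if (stats::runif(1) < m$pause_prob) {
        resting <- TRUE
      }
      if (sqrt(sum((p - wp)^2)) < 2) wp <- draw_waypoint()
      goal <- atan2(wp[2] - p[2], wp[1] - p[1])
      theta <- goal + wrap_angle(theta - goal) * 0.7 +
        stats::rnorm(1, 0, m$turn_sd)
      v <- m$mean_speed + m$speed_ac * (v - m$mean_speed) +
        stats::rnorm(1, 0, m$speed_sd * sqrt(1 - m$speed_ac^2))
      v <- max(v, 0)
      step <- if (resting) stats::runif(1, 0, 0.8) * dt else v * dt
      cand <- p + step * c(cos(theta), sin(theta))
      if (!inside(cand)) {
        cand <- clamp_in(cand)
        wp <- draw_waypoint()
      }
      p <- cand
      h <- clamp_in(p + m$head_offset * c(cos(theta), sin(theta)), slack = 0.1)
      bx[i] <- p[1]; by[i] <- p[2]; hx[i] <- h[1]; hy[i] <- h[2]
    }
    tibble::tibble(frame = seq_len(n) - 1L, time = (seq_len(n) - 1L) * dt,
                   head_x = hx, head_y = hy, body_x = bx, body_y = by)
  })
}

#' Spatial bin occupancy of a trajectory
#'
#' Counts time spent in each square spatial bin over the arena bounding box.
#'
#' @param tracking Tibble from [simulate_trajectory()] (head position used).
#' @param geometry An [arena_geometry()] object.
#' @param bin_size Bin side in cm.
#' @param frame_rate Frames per second.
#' @return Tibble with bin centres `x`, `y`, occupancy `seconds` and a flag
#'   `in_arena` for bins whose centre lies inside the octagon.
#' @export
bin_occupancy <- function(tracking, geometry, bin_size = 2, frame_rate = 20) {
  g <- map_grid(geometry, bin_size)
  idx <- grid_index(tracking$head_x, tracking$head_y, g)
  counts <- tabulate(idx, nbins = g$nbin)
  tibble::tibble(x = g$centers_x, y = g$centers_y,
                 seconds = counts / frame_rate,
                 in_arena = g$inside)
}
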