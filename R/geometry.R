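#' Octagonal arena geometry
#'
#' Builds the geometry of the regular octagonal arena used throughout the
#' pipeline: eight walls, each carrying a liquid-reward port at its midpoint
#' and (context-dependently) a strip of light cues. Walls are indexed 0..7
#' counter-clockwise starting at the east wall, so that wall `k` has outward
#' normal angle `k * 45` degrees (0 = E, 1 = NE, 2 = N, ..., 7 = SE).
#'
#' Contexts are defined by which walls carry light cues; each context has one
#' rewarded wall. In the discrimination paradigm the two contexts reward
#' different walls; in the generalization paradigm both contexts reward the
#' same wall.
#'
#' @param radius Circumradius of the octagon in cm (distance from centre to a
#'   vertex). Default 20.
#' @param paradigm `"discrimination"` or `"generalization"`.
#' @param lightcue_walls Named list with one integer vector of wall ids per
#'   context. Defaults: discrimination A = E/NE, B = N/NW; generalization
#'   C = W/SW, D = S/SE.
#' @param reward_walls Named integer vector, one rewarded wall id per context.
#'   Defaults: discrimination A = west (4), B = east (0); generalization both
#'   contexts = north (2).
#' @param reference Numeric length-2, the reference point \eqn{(R_X, R_Y)} for
#'   egocentric directional analysis. Default the arena centre `c(0, 0)`.
#'
#' @return An object of class `remap_arena`: a list with elements `radius`,
#'   `apothem`, `paradigm`, `contexts` (character length 2), `walls` (a tibble
#'   with wall id, normal angle, port x/y and per-context cue/reward flags),
#'   and `reference`.
#' @examples
#' geom <- arena_geometry()
#' geom$walls
#' @export
arena_geometry <- function(radius = 20,
                           paradigm = c("discrimination", "generalization"),
                           lightcue_walls = NULL,
                           reward_walls = NULL,
                           reference = c(0, 0)) {
  paradigm <- match.arg(paradigm)
  if (!is.numeric(radius) || radius <= 0) {
    stop("`radius` must be a positive number", call. = FALSE)
  }
  contexts <- if (paradigm == "discrimination") c("A", "B") else c("C", "D")
  if (is.null(lightcue_walls)) {
    lightcue_walls <- if (paradigm == "discrimination") {
      list(A = c(0L, 1L), B = c(2L, 3L))
    } else {
      list(C = c(4L, 5L), D = c(6L, 7L))
    }
  }
  if (is.null(reward_walls)) {
    reward_walls <- if (paradigm == "discrimination") {
      c(A = 4L, B = 0L)
    } else {
      c(C = 2L, D = 2L)
    }
  }
  stopifnot(setequal(names(lightcue_walls), contexts),
            setequal(names(reward_walls), contexts))
  all_walls <- unlist(lightcue_walls, use.names = FALSE)
  if (any(all_walls < 0 | all_walls > 7) || any(reward_walls < 0 | reward_walls > 7)) {
    stop("wall ids must lie in 0..7", call. = FALSE)
  }
  if (paradigm == "generalization" &&
      reward_walls[[contexts[1]]] != reward_walls[[contexts[2]]]) {
    stop("in the generalization paradigm the reward wall must be shared by both contexts",
         call. = FALSE)
  }
  apothem <- radius * cos(pi / 8)
  id <- 0:7
  angle <- id * pi / 4
  walls <- tibble::tibble(
    wall = id,
    normal_angle = angle,
    port_x = apothem * cos(angle),
    port_y = apothem * sin(angle),
    lightcue_1 = id %in% lightcue_walls[[contexts[1]]],
    lightcue_2 = id %in% lightcue_walls[[contexts[2]]],
    reward_1 = id == reward_walls[[contexts[1]]],
    reward_2 = id == reward_walls[[contexts[2]]]
  )
  structure(
    list(radius = radius, apothem = apothem, paradigm = paradigm,
         contexts = contexts, walls = walls,
         reference = as.numeric(reference)),
    class = "remap_arena"
  )
}

#' @export
print.remap_arena <- function(x, ...) {
  cat(sprintf("<remap_arena> regular octagon, radius %.1f cm, %s paradigm\n",
              x$radius, x$paradigm))
  cat(sprintf("contexts: %s / %s; reference point (%.1f, %.1f)\n",
              x$contexts[1], x$contexts[2], x$reference[1], x$reference[2]))
  print(x$walls)
  invisible(x)
}

#' Test whether points lie inside the octagon
#'
#' A point is inside the regular octagon iff its projection onto every wall
#' normal is at most the apothem.
#'
#' @param xy Data frame (or matrix) with columns/cols `x` and `y` in cm.
#' @param geometry A [arena_geometry()] object.
#' @param tol Slack in cm allowed beyond the boundary (default 1e-9).
#' @return Logical vector, one per row.
#' @export
in_arena <- function(xy, geometry, tol = 1e-9) {
  if (is.data.frame(xy)) xy <- cbind(xy$x, xy$y)
  ang <- geometry$walls$normal_angle
  proj <- xy %*% rbind(cos(ang), sin(ang))
  apply(proj <= geometry$apothem + tol, 1L, all)
}

#' Reward port coordinates of a geometry
#'
#' @param geometry A [arena_geometry()] object.
#' @return Tibble with `context`, `wall`, `x`, `y`; in the generalization
#'   paradigm the (shared) port appears once per context.
#' @export
reward_ports <- function(geometry) {
  w <- geometry$walls
  dplyr::bind_rows(
    tibble::tibble(context = geometry$contexts[1],
                   wall = w$wall[w$reward_1],
                   x = w$port_x[w$reward_1], y = w$port_y[w$reward_1]),
    tibble::tibble(context = geometry$contexts[2],
                   wall = w$wall[w$reward_2],
                   x = w$port_x[w$reward_2], y = w$port_y[w$reward_2])
  )
}

# wrap angle(s) to [-pi, pi)
wrap_angle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

#' Map angles to wall ids
#'
#' Angular bins are 45 degrees wide, centred on the wall-normal angles, so each
#' bin corresponds to one wall of the octagon.
#'
#' @param angle Angles in radians.
#' @return Integer wall ids in 0..7.
#' @export
angle_to_wall <- function(angle) {
  as.integer(round(wrap_angle(angle) / (pi / 4))) %% 8L
}

#' Wall adjacency test
#'
#' Two walls are adjacent when they are exactly one step apart around the
#' octagon (modulo 8).
#'
#' @param a,b Integer wall ids.
#' @return Logical vector.
#' @export
walls_adjacent <- function(a, b) {
  d <- (a - b) %% 8L
  d == 1L | d == 7L
}
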