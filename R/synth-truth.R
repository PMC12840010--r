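#' Planted ground truth for a synthetic population
#'
#' Draws tuning parameters for a mixed population of place, directional,
#' conjunctive and background (non-coding) cells. Place fields are isotropic
#' 2D Gaussians with per-context gains; `remapping` controls how the two
#' context maps relate: `"none"` (same fields, same gains), `"rate"` (same
#' fields, per-context gains `gain`), or `"global"` (independent field
#' centres per context). Directional tuning is von Mises around a preferred
#' relative direction with concentration `kappa` and modulation depth
#' `depth`, expressed relative to the geometry's reference point.
#'
#' @param geometry An [arena_geometry()] object.
#' @param n_place,n_directional,n_conjunctive,n_background Cell counts per
#'   class.
#' @param n_fields Fields per place/conjunctive cell: a single count or a
#'   vector sampled from uniformly per cell.
#' @param field_width Isotropic Gaussian field width (sd) in cm (default 3).
#' @param amp Field amplitude in events/min at the field centre (default 45).
#' @param baseline Baseline event rate in events/min of place and conjunctive
#'   cells (default 0.05; deconvolved calcium events of CA1 place cells are
#'   strongly concentrated in-field, with only occasional stray events).
#' @param bg_rate Baseline event rate of background and pure directional cells
#'   in events/min (default 6); for directional cells this is the rate that
#'   the von Mises factor modulates.
#' @param remapping `"none"`, `"rate"`, or `"global"`.
#' @param gain Length-2 per-context gains applied to field amplitude under
#'   `remapping = "rate"` (default `c(1, 1)`).
#' @param kappa,depth Von Mises concentration and modulation depth of
#'   directional cells (defaults 2 and 0.8).
#' @param dir_context `"both"`, `"1"` or `"2"`: context(s) in which
#'   directional modulation is expressed.
#' @param min_sep Minimum distance between field centres of one cell in cm
#'   (default 15).
#' @param margin Keep field centres at least this far inside the boundary in
#'   cm (default 3).
#' @param near_wall If `TRUE`, place field centres within 10 cm of the
#'   boundary (used to study occupancy-induced directional bias).
#' @param seed Integer seed.
#' @return A tibble of class `remap_truth`, one row per neuron: `neuron`,
#'   `cell_class`, `baseline`, `remapping`, list-column `fields` (per-field
#'   `center_x`, `center_y`, `center_x2`, `center_y2`, `width`, `amp`,
#'   `gain_1`, `gain_2`) and directional parameters `dir_mu`, `dir_kappa`,
#'   `dir_depth`, `dir_context`.
#' @export
make_ground_truth <- function(geometry,
                              n_place = 0, n_directional = 0,
                              n_conjunctive = 0, n_background = 0,
                              n_fields = 1, field_width = 3, amp = 45,
                              baseline = 0.05, bg_rate = 6,
                              remapping = c("none", "rate", "global"),
                              gain = c(1, 1), kappa = 2, depth = 0.8,
                              dir_context = "both",
                              min_sep = 15, margin = 3, near_wall = FALSE,
                              seed = NULL) {
  remapping <- match.arg(remapping)
  stopifnot(all(gain >= 0), all(field_width > 0), amp > 0)
  classes <- rep(c("place", "directional", "conjunctive", "background"),
                 times = c(n_place, n_directional, n_conjunctive, n_background))
  n <- length(classes)
  if (!n) stop("no cells requested", call. = FALSE)

  with_seed(seed, {
    draw_center <- function() {
      repeat {
        p <- stats::runif(2, -geometry$radius, geometry$radius)
        if (!in_arena(rbind(p), geometry, tol = -margin)) next
        if (near_wall &&
            in_arena(rbind(p), geometry, tol = -10)) next
        return(p)
      }
    }
    draw_centers <- function(k) {
      pts <- matrix(NA_real_, k, 2)
      for (j in seq_len(k)) {
        repeat {
          p <- draw_center()
          if (j == 1 ||
              min(sqrt(rowSums((pts[seq_len(j - 1), , drop = FALSE] -
                                  matrix(p, j - 1, 2, byrow = TRUE))^2))) >= min_sep)
            break
        }
        pts[j, ] <- p
      }
      pts
    }
    rows <- lapply(seq_len(n), function(i) {
      cls <- classes[i]
      has_fields <- cls %in% c("place", "conjunctive")
      flds <- if (has_fields) {
        k <- if (length(n_fields) > 1) sample(n_fields, 1) else n_fields
        ctr <- draw_centers(k)
        ctr2 <- if (remapping == "global") draw_centers(k) else ctr
        g <- if (remapping == "rate") gain else c(1, 1)
        tibble::tibble(center_x = ctr[, 1], center_y = ctr[, 2],
                       center_x2 = ctr2[, 1], center_y2 = ctr2[, 2],
                       width = field_width, amp = amp,
                       gain_1 = g[1], gain_2 = g[2])
      } else {
        tibble::tibble(center_x = numeric(), center_y = numeric(),
                       center_x2 = numeric(), center_y2 = numeric(),
                       width = numeric(), amp = numeric(),
                       gain_1 = numeric(), gain_2 = numeric())
      }
      directional <- cls %in% c("directional", "conjunctive")
      tibble::tibble(
        neuron = i, cell_class = cls,
        baseline = if (cls %in% c("background", "directional")) bg_rate else baseline,
        remapping = if (has_fields) remapping else "none",
        fields = list(flds),
        dir_mu = if (directional) stats::runif(1, -pi, pi) else NA_real_,
        dir_kappa = if (directional) kappa else NA_real_,
        dir_depth = if (directional) depth else 0,
        dir_context = if (directional) dir_context else NA_character_
      )
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("remap_truth", class(out))
    out
  })
}
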