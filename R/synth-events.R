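#' Simulate calcium event trains from planted ground truth
#'
#' Draws per-neuron event trains by thinning an inhomogeneous Poisson process
#' at the frame rate. The instantaneous rate is
#' \deqn{\lambda(t) = \big(b + \sum_f A_f\, g_{c(t),f}\,
#'   e^{-d_f(t)^2 / 2 w_f^2}\big) \cdot m(H_t)}
#' where \eqn{b} is the baseline rate, the sum runs over the cell's planted
#' Gaussian fields (distance \eqn{d_f} from the head to the field centre of
#' the current context, per-context gain \eqn{g}), and for directionally
#' modulated cells \eqn{m(H) = 1 + depth\,(f(H)/\bar f - 1)} is a
#' mean-normalized von Mises gain on the relative running direction \eqn{H}
#' to the geometry's reference point, with \eqn{f(H) \propto
#' e^{\kappa\cos(H - \mu)}} and \eqn{\bar f} its circular mean, so that the
#' planted mean rate is preserved and `depth` is the fractional deviation
#' from uniform tuning (\eqn{m \equiv 1} for untuned cells; the rate is
#' clamped at zero). Frames outside any trial use the average of the two
#' context rates. At most one event is drawn per frame, with probability
#' \eqn{1 - e^{-\lambda \Delta t}}.
#'
#' @param truth A [make_ground_truth()] tibble.
#' @param geometry An [arena_geometry()] object.
#' @param tracking Tracking tibble from [simulate_trajectory()].
#' @param trials Trial tibble from [simulate_trial_sequence()].
#' @param seed Integer seed.
#' @param frame_rate Frames per second.
#' @return Tibble with columns `neuron` and `frame` (0-based, sorted within
#'   neuron).
#' @export
simulate_event_trains <- function(truth, geometry, tracking, trials,
                                  seed = NULL, frame_rate = 20) {
  stopifnot(inherits(geometry, "remap_arena"), nrow(tracking) > 0)
  n <- nrow(tracking)
  dt_min <- 1 / frame_rate / 60  # frame duration in minutes
  ctx_idx <- frame_context_index(trials, geometry$contexts, n)

  # relative running direction per frame (NA where displacement is zero)
  hx <- tracking$head_x; hy <- tracking$head_y
  dx <- c(diff(hx), 0); dy <- c(diff(hy), 0)
  phi <- ifelse(dx == 0 & dy == 0, NA_real_, atan2(dy, dx))
  bear <- atan2(geometry$reference[2] - hy, geometry$reference[1] - hx)
  H <- wrap_angle(phi - bear)

  with_seed(seed, {
    res <- lapply(seq_len(nrow(truth)), function(i) {
      row <- truth[i, ]
      f <- row$fields[[1]]
      r1 <- r2 <- rep(0, n)
      if (nrow(f)) {
        for (j in seq_len(nrow(f))) {
          d1 <- (hx - f$center_x[j])^2 + (hy - f$center_y[j])^2
          d2 <- (hx - f$center_x2[j])^2 + (hy - f$center_y2[j])^2
          r1 <- r1 + f$amp[j] * f$gain_1[j] * exp(-d1 / (2 * f$width[j]^2))
          r2 <- r2 + f$amp[j] * f$gain_2[j] * exp(-d2 / (2 * f$width[j]^2))
        }
      }
      lam <- row$baseline +
        ifelse(is.na(ctx_idx), (r1 + r2) / 2,
               ifelse(ctx_idx == 1L, r1, r2))
      if (!is.na(row$dir_mu) && row$dir_depth > 0) {
        dep <- switch(row$dir_context,
                      both = rep(row$dir_depth, n),
                      `1` = ifelse(!is.na(ctx_idx) & ctx_idx == 1L,
                                   row$dir_depth, 0),
                      `2` = ifelse(!is.na(ctx_idx) & ctx_idx == 2L,
                                   row$dir_depth, 0))
        vm <- exp(row$dir_kappa * (cos(H - row$dir_mu) - 1))
        vm_mean <- besselI(row$dir_kappa, 0) * exp(-row$dir_kappa)
        fac <- 1 + dep * (ifelse(is.na(vm), vm_mean, vm) / vm_mean - 1)
        lam <- pmax(lam * fac, 0)
      }
      stopifnot(all(lam >= 0))
      p <- 1 - exp(-lam * dt_min)
      ev <- which(stats::runif(n) < p)
      tibble::tibble(neuron = row$neuron, frame = as.integer(ev - 1L))
    })
    dplyr::bind_rows(res)
  })
}

# per-frame context index (1, 2 or NA outside trials), 1-based frame positions
frame_context_index <- function(trials, contexts, n_frames) {
  idx <- rep(NA_integer_, n_frames)
  if (is.null(trials) || !nrow(trials)) return(idx)
  for (i in seq_len(nrow(trials))) {
    span <- (trials$start_frame[i]:trials$end_frame[i]) + 1L
    span <- span[span >= 1L & span <= n_frames]
    idx[span] <- match(trials$context[i], contexts)
  }
  idx
}
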