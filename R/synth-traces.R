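#' Simulate calcium traces and deconvolved signals from event trains
#'
#' Convolves each event train with a fast-rise, exponential-decay kernel
#' (decay time constant 0.4 s) and adds Gaussian noise to produce a
#' \eqn{\Delta F/F_0} trace; the deconvolved signal is a unit impulse at each
#' event frame. In `"unstable"` mode a slow baseline drift exceeding 0.1
#' \eqn{\Delta F/F_0} for more than 5 minutes is added, so that downstream
#' quality control labels the trace unstable (sessions of at least ~7 min are
#' needed for the drift to span 5 one-minute sections).
#'
#' @param events Tibble with columns `neuron`, `frame` (0-based).
#' @param n_frames Total number of frames in the session.
#' @param seed Integer seed.
#' @param stability `"stable"` or `"unstable"`.
#' @param noise_sd Noise sd in \eqn{\Delta F/F_0} units (default 0.02).
#' @param frame_rate Frames per second.
#' @return Tibble with columns `neuron`, `frame`, `dff`, `deconv`.
#' @export
simulate_calcium_traces <- function(events, n_frames, seed = NULL,
                                    stability = c("stable", "unstable"),
                                    noise_sd = 0.02, frame_rate = 20) {
  stability <- match.arg(stability)
  stopifnot(n_frames >= 1)
  decay <- exp(-1 / (0.4 * frame_rate))
  neurons <- sort(unique(events$neuron))
  if (!length(neurons)) neurons <- 1L
  t_min <- (seq_len(n_frames) - 1) / frame_rate / 60
  drift <- if (stability == "unstable") {
    # smooth ramp from minute 1 to minute 2, holding at 0.3 dF/F0
    0.3 * stats::plogis((t_min - 1.5) * 6)
  } else {
    rep(0, n_frames)
  }
  with_seed(seed, {
    res <- lapply(neurons, function(id) {
      ev <- events$frame[events$neuron == id] + 1L
      imp <- numeric(n_frames)
      imp[ev] <- 1
      dff <- stats::filter(imp, decay, method = "recursive")
      dff <- as.numeric(dff) + drift + stats::rnorm(n_frames, 0, noise_sd)
      tibble::tibble(neuron = id, frame = seq_len(n_frames) - 1L,
                     dff = dff, deconv = imp)
    })
    dplyr::bind_rows(res)
  })
}
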