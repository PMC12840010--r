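#' Plot a context rate map
#'
#' @param maps Tibble from [context_rate_maps()].
#' @param neuron Neuron id to plot (default: first).
#' @return A ggplot object (one facet per context).
#' @export
plot_rate_map <- function(maps, neuron = NULL) {
  neuron <- neuron %||% maps$neuron[1]
  dat <- dplyr::filter(maps, .data$neuron == !!neuron, .data$valid)
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y, fill = .data$rate)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~context) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "events/min") +
    ggplot2::labs(title = paste("neuron", neuron), x = "x (cm)", y = "y (cm)") +
    ggplot2::theme_minimal()
}

#' Polar plot of a directional tuning curve
#'
#' @param tuning Tibble from [directional_tuning()].
#' @return A ggplot object.
#' @export
plot_tuning_curve <- function(tuning) {
  dat <- dplyr::mutate(tuning, deg = (.data$theta %% (2 * pi)) * 180 / pi)
  ggplot2::ggplot(dat, ggplot2::aes(.data$deg, .data$rate)) +
    ggplot2::geom_col(width = 45, fill = "grey70", colour = "grey30") +
    ggplot2::coord_polar(start = -pi / 8) +
    ggplot2::scale_x_continuous(limits = c(-22.5, 337.5),
                                breaks = seq(0, 315, 45)) +
    ggplot2::labs(x = "relative running direction (deg)",
                  y = "events/min") +
    ggplot2::theme_minimal()
}

#' Cumulative distribution of between-context spatial correlations
#'
#' @param remapping Tibble from [remapping_correlation()] (optionally with a
#'   `group` column to overlay cohorts/paradigms).
#' @return A ggplot object.
#' @export
plot_remapping_cdf <- function(remapping) {
  dat <- dplyr::filter(remapping, !is.na(.data$r))
  aes <- if ("group" %in% names(dat)) {
    ggplot2::aes(.data$r, colour = .data$group)
  } else {
    ggplot2::aes(.data$r)
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "spatial correlation (r)", y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' Cumulative distribution of field rate overlap scores
#'
#' @param fields Tibble from [field_rate_overlap()] (optionally grouped).
#' @return A ggplot object.
#' @export
plot_overlap_cdf <- function(fields) {
  dat <- dplyr::filter(fields, !is.na(.data$overlap))
  aes <- if ("group" %in% names(dat)) {
    ggplot2::aes(.data$overlap, colour = .data$group)
  } else {
    ggplot2::aes(.data$overlap)
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "rate overlap score", y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' Bar summary of decoding accuracy by subset
#'
#' @param decoding Tibble from [decode_by_subset()].
#' @return A ggplot object.
#' @export
plot_decoding <- function(decoding) {
  ggplot2::ggplot(decoding,
                  ggplot2::aes(.data$cell_subset, .data$cv_accuracy,
                               fill = .data$trial_subset)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "cell subset", y = "mean CV accuracy") +
    ggplot2::theme_minimal()
}

#' Histogram of field counts by distance class
#'
#' @param hist_tbl Tibble from [field_distance_histogram()].
#' @return A ggplot object.
#' @export
plot_field_histogram <- function(hist_tbl) {
  hist_tbl$distance_class <- factor(hist_tbl$distance_class,
                                    levels = unique(hist_tbl$distance_class))
  ggplot2::ggplot(hist_tbl,
                  ggplot2::aes(.data$distance_class, .data$n,
                               fill = .data$paradigm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "distance from reward (cm)", y = "fields") +
    ggplot2::theme_minimal()
}
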