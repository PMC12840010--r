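#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a context-decoding result
#'
#' @param x A `remap_decoding` object from [fit_context_decoder()].
#' @param ... Unused.
#' @return Tibble in long form: one row per reported accuracy metric.
#' @export
tidy.remap_decoding <- function(x, ...) {
  tibble::tibble(
    metric = c("cv_accuracy", "holdout_accuracy"),
    estimate = c(x$cv_accuracy, x$holdout_accuracy)
  )
}

#' One-row summary of a context-decoding result
#'
#' @param x A `remap_decoding` object.
#' @param ... Unused.
#' @return One-row tibble with accuracies, kernel scale and problem size.
#' @export
glance.remap_decoding <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("cv_accuracy", "holdout_accuracy",
                                 "kernel_scale", "n_rows", "n_cells")])
}

#' Tidy a pipeline bundle
#'
#' @param x A `remap_bundle` from [run_pipeline()].
#' @param ... Unused.
#' @return Tibble of neuron-level results: place-cell flags, remapping
#'   correlation, DC flags.
#' @export
tidy.remap_bundle <- function(x, ...) {
  pc <- dplyr::distinct(x$place_cells, .data$neuron, .data$is_place_cell)
  out <- dplyr::left_join(pc, x$remapping, by = "neuron")
  dplyr::left_join(out,
                   dplyr::select(x$directional_cells, "neuron", "is_DC",
                                 "is_conjunctive"),
                   by = "neuron")
}

#' One-row summary of a pipeline bundle
#'
#' @param x A `remap_bundle`.
#' @param ... Unused.
#' @return One-row tibble: cell counts, median remapping correlation,
#'   decoding accuracy (all-cells, all-trials row, if run).
#' @export
glance.remap_bundle <- function(x, ...) {
  pc <- dplyr::distinct(x$place_cells, .data$neuron, .data$is_place_cell)
  dec <- NA_real_
  if (!is.null(x$decoding) && nrow(x$decoding)) {
    row <- dplyr::filter(x$decoding, .data$cell_subset == "all",
                         .data$trial_subset == "all")
    if (nrow(row)) dec <- row$cv_accuracy[1]
  }
  tibble::tibble(
    n_neurons = nrow(pc),
    n_place_cells = sum(pc$is_place_cell),
    n_fields = if (is.null(x$fields)) 0L else nrow(x$fields),
    n_DC = sum(x$directional_cells$is_DC),
    median_remapping_r = stats::median(x$remapping$r, na.rm = TRUE),
    cv_accuracy = dec
  )
}
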