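#' Run the full analysis pipeline on a session
#'
#' Chains preprocessing, place-cell identification, field segmentation and
#' rate analysis, directional analysis, context decoding and behavioral
#' classification, returning all stage outputs in one bundle. Every output
#' tibble carries the config hash and seed as attributes for provenance,
#' and rerunning with the same seed reproduces every table exactly.
#'
#' @param session A `remap_session` or a dataset directory path (read via
#'   [read_dataset()]).
#' @param config A [remap_config()].
#' @param seed Integer master seed for the shuffle nulls and decoder.
#' @param n_shuffle Shuffles per null (default from `config`; lower it for
#'   quick looks).
#' @param decode Run the SVM decoding stage (default `TRUE`).
#' @return A list of class `remap_bundle` with elements `frames_spatial`,
#'   `frames_decoding`, `place_cells`, `maps`, `remapping`, `fields`,
#'   `directional`, `directional_cells`, `decoding`, `behavior`, `config`,
#'   `seed`, `config_hash`.
#' @export
run_pipeline <- function(session, config = remap_config(), seed = 1,
                         n_shuffle = NULL, decode = TRUE) {
  if (is.character(session)) {
    if (!dir.exists(session)) {
      stop("dataset directory not found: ", session, call. = FALSE)
    }
    for (f in c("tracking.csv", "trials.csv", "geometry.json", "config.json")) {
      if (!file.exists(file.path(session, f))) {
        stop("stage 1 (load): missing dataset file ", f, call. = FALSE)
      }
    }
    session <- read_dataset(session)
  }
  stopifnot(inherits(session, "remap_session"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  speed <- stage("preprocess", compute_speed(session$tracking, config))
  fr_sp <- stage("preprocess",
                 extract_analysis_frames(session, speed, "spatial", config))
  fr_dec <- stage("preprocess",
                  extract_analysis_frames(session, speed, "decoding", config))
  pc <- stage("spatial",
              place_cell_analysis(session, n_shuffle = n_shuffle,
                                  seed = child_seed(seed, 11),
                                  config = config, frames = fr_sp))
  maps <- stage("spatial",
                context_rate_maps(session, config = config, frames = fr_sp))
  remap <- stage("spatial", remapping_correlation(maps))
  pc_flags <- dplyr::distinct(pc, .data$neuron, .data$is_place_cell)
  place_ids <- pc_flags$neuron[pc_flags$is_place_cell]
  flds <- stage("fields", {
    f <- segment_place_fields(session,
                              neurons = if (length(place_ids)) place_ids else
                                integer(),
                              config = config, frames = fr_sp)
    if (nrow(f)) {
      f <- field_rate_overlap(f, maps)
      f <- assign_reward_fields(f, session$geometry, config)
    }
    f
  })
  dres <- stage("directional",
                directional_analysis(session, n_shuffle = n_shuffle,
                                     seed = child_seed(seed, 13),
                                     config = config, frames = fr_sp))
  dcls <- stage("directional",
                classify_directional_cells(dres, pc_flags, config = config))
  dec <- if (decode) {
    stage("decode", decode_by_subset(session, pc_flags,
                                     seed = child_seed(seed, 17),
                                     config = config, frames = fr_dec))
  } else {
    NULL
  }
  beh <- stage("behavior", classify_trials(session$trials, session$geometry))
  bundle <- list(frames_spatial = fr_sp, frames_decoding = fr_dec,
                 place_cells = pc, maps = maps, remapping = remap,
                 fields = flds, directional = dres,
                 directional_cells = dcls, decoding = dec, behavior = beh,
                 paradigm = session$paradigm,
                 config = config, seed = seed,
                 config_hash = config_hash(config))
  class(bundle) <- "remap_bundle"
  bundle
}

#' @export
print.remap_bundle <- function(x, ...) {
  cat(sprintf("<remap_bundle> config %s, seed %s\n", x$config_hash,
              format(x$seed)))
  cat(sprintf("  %d neurons analysed, %d place cells, %d fields, %d DCs\n",
              length(unique(x$place_cells$neuron)),
              sum(dplyr::distinct(x$place_cells, .data$neuron,
                                  .data$is_place_cell)$is_place_cell),
              if (is.null(x$fields)) 0L else nrow(x$fields),
              sum(x$directional_cells$is_DC)))
  invisible(x)
}

#' Standard two-group comparisons
#'
#' Thin wrappers over the standard tests used for reporting: Wilcoxon rank
#' sum (with normal-approximation z), Kolmogorov-Smirnov, paired t, and
#' chi-squared, with optional Bonferroni correction.
#'
#' @param values_a,values_b Numeric samples (for `chi2`: counts and expected
#'   proportions).
#' @param test One of `"ranksum"`, `"ks"`, `"paired_t"`, `"chi2"`.
#' @param n_comparisons Bonferroni divisor (default 1).
#' @return One-row tibble with `test`, `statistic`, `p_value`, `p_adjusted`.
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("ranksum", "ks", "paired_t", "chi2"),
                           n_comparisons = 1) {
  test <- match.arg(test)
  if (test != "chi2" && (!length(values_a) || !length(values_b))) {
    stop("empty sample", call. = FALSE)
  }
  res <- switch(test,
    ranksum = {
      ht <- stats::wilcox.test(values_a, values_b, exact = FALSE,
                               correct = FALSE)
      n1 <- length(values_a); n2 <- length(values_b)
      z <- (ht$statistic - n1 * n2 / 2) /
        sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
      c(stat = unname(z), p = ht$p.value)
    },
    ks = {
      ht <- suppressWarnings(stats::ks.test(values_a, values_b))
      c(stat = unname(ht$statistic), p = ht$p.value)
    },
    paired_t = {
      if (length(values_a) != length(values_b)) {
        stop("paired test needs equal-length samples", call. = FALSE)
      }
      ht <- stats::t.test(values_a, values_b, paired = TRUE)
      c(stat = unname(ht$statistic), p = ht$p.value)
    },
    chi2 = {
      ht <- stats::chisq.test(values_a, p = values_b / sum(values_b))
      c(stat = unname(ht$statistic), p = ht$p.value)
    }
  )
  tibble::tibble(test = test, statistic = res[["stat"]],
                 p_value = res[["p"]],
                 p_adjusted = pmin(1, res[["p"]] * n_comparisons))
}

#' Write a report of figure tables and plots
#'
#' Emits the figure-level summaries of a result bundle as delimited tables
#' plus ggplot figures: cumulative distributions of the between-context
#' spatial correlation and of field rate overlap, the decoding accuracy
#' summary, the field-distance histogram and the directional tuning
#' composition. Every table embeds the config hash and seed columns; reruns
#' with the same bundle are byte-identical. Missing stages produce
#' explicit empty tables rather than errors.
#'
#' @param bundle A `remap_bundle` from [run_pipeline()].
#' @param dir Output directory.
#' @param write_figures Also write PDF figures (default `FALSE`; tables are
#'   always written).
#' @return Invisibly, the list of written file paths.
#' @export
write_report <- function(bundle, dir, write_figures = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  stamp <- function(tbl) {
    if (is.null(tbl) || !nrow(tbl)) {
      tbl <- tibble::tibble(note = "empty panel: no data at this stage")
    }
    dplyr::mutate(tbl, config_hash = bundle$config_hash, seed = bundle$seed)
  }
  emit <- function(tbl, name) {
    path <- file.path(dir, name)
    readr::write_csv(stamp(tbl), path)
    written <<- c(written, path)
  }
  emit(bundle$remapping, "spatial_correlation.csv")
  if (!is.null(bundle$fields) && nrow(bundle$fields)) {
    emit(dplyr::select(bundle$fields, -dplyr::any_of("pixels")), "fields.csv")
    emit(field_distance_histogram(bundle$fields, bundle$paradigm),
         "field_distance_histogram.csv")
  } else {
    emit(NULL, "fields.csv")
    emit(NULL, "field_distance_histogram.csv")
  }
  emit(dplyr::select(bundle$place_cells, -dplyr::any_of("curve")),
       "place_cells.csv")
  emit(dplyr::select(bundle$directional, -dplyr::any_of("curve")),
       "directional.csv")
  emit(bundle$directional_cells, "directional_cells.csv")
  emit(bundle$decoding, "decoding.csv")
  emit(dplyr::count(bundle$behavior, .data$outcome_check, .data$error_type),
       "behavior_summary.csv")
  if (write_figures) {
    figs <- list(
      spatial_correlation_cdf = plot_remapping_cdf(bundle$remapping),
      rate_overlap_cdf = if (!is.null(bundle$fields) &&
                             nrow(bundle$fields)) {
        plot_overlap_cdf(bundle$fields)
      },
      decoding = if (!is.null(bundle$decoding)) {
        plot_decoding(bundle$decoding)
      }
    )
    for (nm in names(figs)) {
      if (is.null(figs[[nm]])) next
      path <- file.path(dir, paste0(nm, ".pdf"))
      ggplot2::ggsave(path, figs[[nm]], width = 5, height = 4)
      written <- c(written, path)
    }
  }
  invisible(written)
}
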