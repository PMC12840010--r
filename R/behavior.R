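#' Classify trial outcomes and error types
#'
#' A trial is correct when the visited port is the rewarded wall of its
#' context, a timeout when no port was visited. Incorrect trials are typed
#' with precedence context > spatial precision > non-specific: a context
#' error when the visited port is the one rewarded in the other context, a
#' spatial precision error when it is adjacent (one wall either side) to the
#' correct port, and non-specific otherwise. In the generalization paradigm
#' the two contexts share the reward, so context errors cannot occur.
#'
#' @param trials Trial tibble (columns `context`, `outcome`,
#'   `visited_port`).
#' @param geometry An [arena_geometry()] object.
#' @return `trials` with added columns `outcome_check` (recomputed outcome)
#'   and `error_type` (`NA`, `"context"`, `"spatial_precision"` or
#'   `"non_specific"`).
#' @export
classify_trials <- function(trials, geometry) {
  ctxs <- geometry$contexts
  rw <- stats::setNames(
    c(geometry$walls$wall[geometry$walls$reward_1],
      geometry$walls$wall[geometry$walls$reward_2]), ctxs)
  own <- rw[trials$context]
  other <- rw[ifelse(trials$context == ctxs[1], ctxs[2], ctxs[1])]
  visited <- trials$visited_port
  if (any(is.na(visited) & trials$outcome != "timeout")) {
    stop("malformed trial record: missing visited port on a non-timeout trial",
         call. = FALSE)
  }
  outcome <- dplyr::case_when(
    is.na(visited) ~ "timeout",
    visited == own ~ "correct",
    TRUE ~ "incorrect"
  )
  err <- dplyr::case_when(
    outcome != "incorrect" ~ NA_character_,
    visited == other & other != own ~ "context",
    walls_adjacent(visited, own) ~ "spatial_precision",
    TRUE ~ "non_specific"
  )
  dplyr::mutate(trials, outcome_check = outcome, error_type = err)
}

#' Chi-squared test of error composition against a baseline
#'
#' Pearson chi-squared of observed category counts against expectations
#' derived from baseline proportions (e.g. the error composition of
#' unmanipulated animals), with optional Bonferroni correction across
#' sessions. The category set is configurable: the three error types alone,
#' or five categories including correct and timeout. Categories with zero
#' expected counts are pooled into the largest category with a warning.
#'
#' @param observed Named numeric vector (or tibble with `category`, `n`) of
#'   observed counts.
#' @param baseline Proportions over the same categories (normalized
#'   internally).
#' @param n_comparisons Bonferroni divisor applied to the p value
#'   (default 1).
#' @return One-row tibble with `statistic`, `df`, `p_value`,
#'   `p_adjusted`.
#' @examples
#' error_composition(c(context = 16, spatial_precision = 2, non_specific = 2),
#'                   c(context = 0.5, spatial_precision = 0.25,
#'                     non_specific = 0.25))
#' @export
error_composition <- function(observed, baseline, n_comparisons = 1) {
  if (is.data.frame(observed)) {
    observed <- stats::setNames(observed$n, observed$category)
  }
  stopifnot(all(names(observed) %in% names(baseline)))
  baseline <- baseline[names(observed)]
  baseline <- baseline / sum(baseline)
  if (any(baseline == 0)) {
    warning("zero expected count; pooling into the largest category",
            call. = FALSE)
    big <- which.max(baseline)
    zero <- baseline == 0
    observed[big] <- observed[big] + sum(observed[zero])
    observed <- observed[!zero]
    baseline <- baseline[!zero]
  }
  n <- sum(observed)
  expected <- n * baseline
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p_value = p,
                 p_adjusted = pmin(1, p * n_comparisons))
}

#' Behavioral summary and days-to-criterion
#'
#' Per-session fraction of correct non-cued trials, error counts by type,
#' and the first session reaching the 70% performance criterion.
#'
#' @param sessions Tibble of classified trials with a `day` column (from
#'   [classify_trials()], one block per training day).
#' @param config A [remap_config()].
#' @return List with `by_day` (tibble: `day`, `n_trials`, `fraction_correct`,
#'   error counts, `timeouts`) and `days_to_criterion` (first day at or
#'   above criterion, or `NA` if never reached).
#' @export
performance_summary <- function(sessions, config = remap_config()) {
  noncued <- dplyr::filter(sessions, !.data$cued)
  if (!nrow(noncued)) stop("no non-cued trials", call. = FALSE)
  by_day <- noncued |>
    dplyr::group_by(day = .data$day) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      fraction_correct = mean(.data$outcome_check == "correct"),
      context_errors = sum(.data$error_type == "context", na.rm = TRUE),
      spatial_precision_errors = sum(.data$error_type == "spatial_precision",
                                     na.rm = TRUE),
      non_specific_errors = sum(.data$error_type == "non_specific",
                                na.rm = TRUE),
      timeouts = sum(.data$outcome_check == "timeout"),
      .groups = "drop") |>
    dplyr::arrange(.data$day)
  hit <- which(by_day$fraction_correct >= config$criterion)
  list(by_day = by_day,
       days_to_criterion = if (length(hit)) by_day$day[hit[1]] else NA_integer_)
}
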