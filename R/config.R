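#' Analysis configuration with standard defaults
#'
#' Collects every tunable threshold of the pipeline in one place. Defaults are
#' the values used throughout the analysis: 20 Hz master clock, 2 cm/s running
#' threshold, 167 ms position smoothing, 2x2 cm spatial bins smoothed with a
#' sigma = 3 cm Gaussian, 0.1 s bin-occupancy validity floor, 0.4 stability
#' floor with a 95th-percentile shuffle criterion (500 circular shuffles, >= 1
#' min shift), 10-event session floor, 1 event/min peak prominence and 20%
#' of-peak field cutoff, 10 cm reward-field radius with 5 cm distance bins,
#' +/-0.33 firing-preference cutoffs, 45 degree direction bins, 60-frame
#' decoder windows with every-20th-frame thinning, an 80/20 train/test split
#' and 20-fold cross-validation, and the 70% behavioral criterion.
#'
#' @param ... Named overrides of any default listed above.
#' @return A named list of class `remap_config`.
#' @examples
#' cfg <- remap_config(bin_size = 4)
#' cfg$bin_size
#' @export
remap_config <- function(...) {
  cfg <- list(
    frame_rate = 20,            # Hz, master clock
    speed_smooth_ms = 167,      # moving-average width for position smoothing
    run_speed = 2,              # cm/s locomotion threshold
    bin_size = 2,               # cm, spatial bin side
    map_sigma = 3,              # cm, Gaussian smoothing of maps
    min_occupancy = 0.1,        # s, bin validity floor
    stability_floor = 0.4,      # absolute correlation criterion
    null_quantile = 0.95,       # shuffle-null criterion
    n_shuffle = 500,            # circular shuffles
    shuffle_margin = 60,        # s, minimum circular shift
    min_events = 10,            # per-session event floor
    qc_valley = 0.1,            # dF/F0 valley threshold
    qc_minutes = 5,             # minutes above valley threshold -> unstable
    peak_prominence = 1,        # events/min, field peak detection
    field_cutoff = 0.2,         # fraction of field peak retained
    min_field_events = 2,       # events attributed to a field
    reward_radius = 10,         # cm, reward-field radius
    distance_bin = 5,           # cm, field-distance increments
    preference_cutoff = 0.33,   # match/mismatch cutoffs
    direction_bins = 8,         # 45 degree bins
    decoder_window = 60,        # frames summed per window
    decoder_thin = 20,          # keep every 20th restricted frame
    train_fraction = 0.8,       # 80/20 split
    cv_folds = 20,              # folds for kernel-scale tuning
    svm_cost = 1,               # fixed regularization
    criterion = 0.7             # behavioral performance criterion
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cfg[names(dots)] <- dots
  }
  num <- vapply(cfg, is.numeric, logical(1))
  if (any(!num) || any(unlist(cfg) <= 0)) {
    stop("all configuration values must be positive numbers", call. = FALSE)
  }
  structure(cfg, class = c("remap_config", "list"))
}

#' @export
print.remap_config <- function(x, ...) {
  cat("<remap_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# stable short hash of a config, embedded in outputs for provenance
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) format(v, digits = 12),
                                character(1)),
             sep = "=", collapse = ";")
  # 31-bit polynomial rolling hash of the serialized key=value string
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
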