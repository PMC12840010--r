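Package: remapflow
Title: Quantifying Hippocampal Context Remapping from Calcium Imaging Sessions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pipeline for analysing hippocampal CA1 context coding in a
    two-context foraging task run in an octagonal arena: trace quality control
    and calcium event handling, occupancy-normalized context rate maps with
    split-half stability and circular-shuffle null tests for place-cell
    identification, Gaussian-mixture place-field segmentation with rate-overlap
    and reward-field statistics, egocentric directional tuning with Rayleigh
    statistics, dual shuffle nulls and a reconstruction-based direction/place
    index, support-vector-machine decoding of context from binned population
    activity, and trial-outcome/error-taxonomy summaries. Includes a synthetic
    session generator (trajectories, trial schedules, inhomogeneous-Poisson
    event trains, calcium traces) with planted ground truth for calibration and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    e1071,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
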