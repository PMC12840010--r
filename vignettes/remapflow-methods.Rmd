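---
title: "Quantifying hippocampal context coding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hippocampal context coding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remapflow)
```

remapflow analyses CA1 calcium-imaging recordings from a two-context
foraging task in an octagonal arena, quantifying how strongly the
hippocampal population distinguishes the two contexts: through spatial
remapping of place cells, rate remapping of individual place fields,
egocentric directional (vector) coding, and population decoding. This
vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and what the bundled synthetic data can
and cannot establish.

## The task and the data model

Each recording session is a sequence of trials in a regular octagonal arena
(circumradius 20 cm) whose eight walls carry reward ports; light cues on a
context-specific pair of walls define the current context. A trial begins
with a *foraging phase* — the animal searches for a hidden 7 x 7 cm trigger
zone, placed at random and armed 10 s after trial start — and ends with a
*reward-retrieval phase* in which the animal must visit the port rewarded
in the current context (60 s timeout). In the discrimination paradigm the
two contexts reward different ports; in the generalization paradigm they
share one port. All neural analyses use foraging-phase data only, so that
reward consumption never contributes.

A session (`remap_session`) holds head/body tracking, the trial table,
per-neuron calcium event trains (frame indices), the arena geometry and,
for synthetic sessions, the planted ground truth. Everything runs on one
master clock at 20 Hz; recorded tracking acquired on a different clock must
be resampled to the imaging clock before analysis. Inter-trial-interval
frames (3 s) belong to no trial and are excluded from every analysis.

## The synthetic-data generator

The generator stands in for the recorded dataset and defines the study
conditions of all calibration and recovery results.

* **Trajectory** — a waypoint-seeking correlated random walk at 20 Hz:
  autocorrelated speed (mean 9 cm/s, per-frame autocorrelation 0.9),
  heading noise, brief resting bouts (speed < 2 cm/s, ~8% of time), and a
  quarter of waypoints drawn near the perimeter, mirroring rodent
  thigmotaxis. Over a default 40-minute session the walk occupies more than
  90% of the 2 x 2 cm bins for at least 0.5 s, which dense-coverage
  spatial analysis requires.
* **Trials** — context labels are balanced within every consecutive pair
  and shuffled within pairs, so any schedule prefix is balanced within one
  trial. Trigger-zone entry terminates foraging; a configurable agent
  (perfect / random-port / biased) resolves the retrieval phase. The
  default session is 40 min with ~70 trials, the 1-hour, 70–100-trial
  session structure scaled to desk size.
* **Event trains** — inhomogeneous Poisson thinning at the frame rate with
  \(\lambda(t) = \big(b + \sum_f A_f\, g_{c(t),f}\,
  e^{-d_f(t)^2/2w_f^2}\big)\, m(H_t)\). Place and conjunctive cells carry
  isotropic Gaussian fields (width \(w\) = 3 cm sd, amplitude \(A\) = 45
  events/min, baseline \(b\) = 0.05 events/min). The sparse out-of-field
  baseline reflects deconvolved CA1 calcium events, which are strongly
  concentrated in-field; it is also what makes the two-event field floor
  meaningful (an isolated stray event produces a near-threshold bump in a
  smoothed map, and the floor removes it). Rate remapping multiplies field
  amplitude by per-context gains; global remapping draws independent field
  centres per context. Directional cells (baseline 6 events/min) are
  modulated by \(m(H) = 1 + depth\,(f(H)/\bar f - 1)\) with \(f\) a von
  Mises density in the relative running direction; the mean-normalized form
  preserves the planted mean rate exactly and makes `depth` the fractional
  deviation from uniform tuning (`depth = 0.8`, \(\kappa = 2\) by
  default).
* **Traces** — events convolved with an instant-rise, 0.4-s-decay kernel
  plus Gaussian noise (sd 0.02 ΔF/F0); the unstable mode adds a slow 0.3
  ΔF/F0 drift that the valley-based QC rule flags.

What the generator does **not** emulate: biomechanically realistic
locomotion, raw imaging movies, reward-consumption dynamics, slow
representational drift, theta-scale temporal structure, or correlated
noise across neurons. Passing recovery tests on these data therefore
demonstrates that the estimators are correct and calibrated under the
assumed statistical structure — not that real recordings satisfy that
structure.

## Preprocessing

* **Trace QC** — traces are cut into non-overlapping 1-min sections; if the
  section minimum ("valley") exceeds 0.1 ΔF/F0 in at least five sections,
  the trace is unstable and excluded. Traces shorter than one section are
  stable by vacuity (with a warning). A manual-verification step is
  replaced by an explicit override: callers may drop neurons by id.
* **Events** — peaks of the deconvolved signal above a configurable
  prominence; plateau peaks collapse to their earliest frame.
* **Speed** — body position smoothed with a 167 ms moving average (3
  frames at 20 Hz; the window rounds to the nearest odd frame count), then
  displacement x frame rate, last value replicated.
* **Analysis frames** — the foraging phase starts at the first single
  frame with speed > 2 cm/s after trial start (no sustained-duration
  requirement) and ends at the trigger frame. Spatial analyses keep only
  running frames; decoding keeps resting frames too. Events on excluded
  frames are dropped from that analysis, never shifted.

## Context rate maps, stability, and the place-cell test

Running foraging frames of all same-context trials are concatenated.
Position is binned at 2 x 2 cm over the arena bounding box; a bin is valid
if its centre lies in the octagon and its raw occupancy is at least 0.1 s
(the threshold suppresses unstable rate estimates in rarely visited
corners). Event counts and occupancy are each smoothed with a Gaussian
kernel (sigma = 3 cm) whose support is restricted to valid bins and whose
columns are normalized — so smoothing conserves total counts exactly — and
the rate map is their ratio in events/min.

Spatial stability splits each context's trials into first/second half (by
trial, not raw frames) and even/odd trials, rebuilds half-maps, and
averages the two Pearson correlations over bins valid in both halves.
Correlations of constant maps are undefined and propagate as failures,
never as zeros. The null distribution circularly shifts event positions
within the concatenated frame sequence by a uniform offset at least 1 min
from the original (500 shuffles). A neuron is a **place cell** if its
stability exceeds both the null's 95th percentile and the absolute floor
0.4 in at least one context, and it fired at least 10 events in the
session. The 0.4 floor is applied to r itself (not its Fisher z, which is
recorded for reporting; the transform is monotone, so classification is
unaffected). On homogeneous-Poisson cells the test's false-positive rate
is bounded by the two one-sided 5% tests and further reduced by the floor;
the packaged calibration study measures it at about 5% (200 cells).

**Remapping** between contexts is the Pearson correlation of the two
smoothed context maps over bins valid in both (at least 10 shared bins).

## Place fields: segmentation and rate analysis

Events of both contexts are pooled and the full map rebuilt. The number of
fields k is the number of 2D local maxima with topographic prominence of
at least 1 event/min, computed on the smoothed pooled map by a
descending-threshold union-find (persistence); plateau peaks collapse to
their earliest-index bin. A k-component Gaussian mixture with full
covariances is then fitted to the rate surface — bin centres weighted by
rate, components initialized at the detected peaks — by a weighted EM
(ridge-regularized at the bin scale); pixels go to the component of
maximal responsibility, pixels below 20% of their field's peak are
removed, and fields with peak < 1 event/min or fewer than two attributed
events are discarded. The 20% cutoff uses the pooled-map field peak, since
segmentation is performed on the pooled map. If the EM degenerates, pixels
fall back to nearest-peak assignment with a logged message. A declarative
overrides list (drop/merge) replaces interactive curation, keeping the
step auditable.

Per field, the mean rate over member pixels in each context map gives the
**rate overlap score** \(1 - |rate_1 - rate_2|/(rate_1 + rate_2)\): 1 for
identical rates, 0 for complete rate remapping. Fields whose centre
(mixture component mean) lies within 10 cm of a rewarded port are **reward
fields** (the closer port counts when two are rewarded); others fall into
5 cm distance bins. Reward-field **firing preference**, computed on maps
rebuilt from correct non-cued trials only, is
\((rate_1 - rate_2)/(rate_1 + rate_2)\cdot(-1)^{k+1}\) with k the index of
the hosting reward; above +0.33 the field is a *match*, below −0.33 a
*mismatch*, otherwise *neutral*. With two antipodal reward ports the
geometry admits field centres slightly beyond 25 cm from both; the
distance histogram warns rather than aborts in that case.

## Directional (vector) coding

With head position smoothed by the same 167 ms filter, the heading
\(\varphi\) and the bearing \(a\) to a reference point \((R_X, R_Y)\) are
quadrant-aware arctangents (a plain arctangent of a coordinate ratio is
quadrant-ambiguous), and the relative running direction is
\(H = ((\varphi - a + \pi) \bmod 2\pi) - \pi\). The reference point is
configurable per run and defaults to the arena centre; per-landmark runs
use cue or reward references. Tuning curves are event rates in eight
45-degree bins of H centred on the wall normals; the Rayleigh vector
\(\sum_b r_b e^{i\theta_b} / \sum_b r_b\) gives tuning strength (length)
and direction (angle); zero-occupancy bins are excluded from the sum.

Significance uses two circular-shift nulls (500 shuffles each): shifting
the events, and shifting the direction series relative to the events. The
second shuffle is a circular shift rather than a frame-wise permutation
because permutation destroys the direction series' autocorrelation and
overstates significance; a cell must beat the 95th percentile of **both**
nulls. Stability mirrors the spatial split-half rule (threshold 0.4 on the
8-bin curve correlation).

Because occupancy is not uniform (animals spend time along walls, which
restricts heading), an apparently tuned curve can be a pure place effect.
The reconstruction analysis disambiguates: with the joint occupancy
\(p(x,y,H)\), the curve expected from the place map alone is
\(r'(H) = \sum_{xy} p\,r(x,y)/\sum_{xy} p\), the map expected from the
curve alone is \(r'(x,y) = \sum_H p\,r(H)/\sum_H p\), and each is compared
with its observation via
\(Error = \langle(obs - rec)^2\rangle / (\max obs - \min obs)\) after
normalizing both to their own peak (the mean runs over valid bins; the
denominator comes from the normalized observed map; a flat observed map
makes the error undefined and the cell fails). The **direction/place
index** is the place-assumption error over the direction-assumption error;
a genuinely directional cell has index > 1. A **directional modulated
cell (DC)** is stable, significant under both nulls, and has index > 1,
all in the same context, with at least 10 session events; DCs that are
also place cells are **conjunctive**. For cells tuned in both contexts the
wrapped angular difference of the Rayleigh angles is reported. Landmark
tuning maps the Rayleigh angle to the nearest wall and categorizes it as
reward / light cue / other; walls carrying both a cue and a reward are
excluded from cells and chance alike, and chance is the wall-count
proportion after exclusion.

In the packaged disambiguation study, planted von Mises cells
(\(\kappa = 2\), depth 0.8) are detected as DCs with full sensitivity,
while pure place cells with near-wall fields on a wall-biased trajectory
are classified DC in well under 20% of cases — the index is what rescues
them.

## Population decoding

Per-cell event series are summed over non-overlapping 60-frame windows
aligned to session start (every frame carries its window's sum), restricted
to foraging frames (running and resting), then thinned to every 20th
retained frame (1 sample/s). An RBF-kernel SVM decodes context: columns
z-scored, a seeded stratified 80/20 train/test split, the kernel scale
tuned by 20-fold cross-validation over a 9-point logarithmic grid centred
on the median-pairwise-distance heuristic, and the regularization constant
fixed at 1 (only the kernel scale is tuned). The mean cross-validated
accuracy of the selected scale is the headline number; the 20% hold-out
accuracy is reported separately as an overfitting check, since it is
ambiguous which of the two a summary accuracy refers to.

Two methodological notes, both visible in the calibration study. First,
because windows span 3 s and rows are 1 s apart, up to three rows share
one window's identical feature vector; under the standard random-row
split such near-duplicates straddle train and test, so even context-blind
Poisson cells decode far above chance by row memorization. The standard
protocol is kept as the default (it is what the headline accuracy refers
to), and a trial-blocked variant (`blocked_split = TRUE`, blocking both
the 80/20 split and the CV folds) is provided; comparisons of
*information content* — place versus non-place subsets — use the blocked
variant. Second, chance level equals the majority-class row fraction, not
0.5, whenever the contexts' foraging durations differ; the label-shuffle
control therefore runs on a context-balanced row subsample, pinning chance
at 0.5 (measured 0.53 over 20 shuffle seeds, within the binomial noise of
the selection-over-grid step).

## Behavior

A trial is *correct* when the visited port is the context's rewarded wall
and a *timeout* when no port was visited. Incorrect trials are typed
*context error* (the port rewarded in the other context), *spatial
precision error* (adjacent to the correct port, one wall either side), or
*non-specific*, with precedence context > spatial precision >
non-specific: with some reward geometries one port satisfies two
definitions and the tie must break deterministically. Error-composition
tests are Pearson chi-squared against baseline proportions with optional
Bonferroni correction; the category set is configurable (three error
types, or five including correct and timeout — a five-category test has
df = 4). Learning curves report the fraction of correct non-cued trials
per day and the first day at or above the 70% criterion.

## Problem sizes and runtime choices

The packaged studies run at desk scale, chosen so the full suite completes
in minutes on one CPU: null calibration with 200 Poisson cells at 500
shuffles on 4 cm map bins (coarser bins quadruple the per-shuffle speed
and leave the test's calibration unchanged); field recovery with 100
cells on one shared 40-minute session; remapping recovery with 30-cell
populations; the decoder at 50 cells x 40 min (and 25 cells x 20 min for
the 20-seed shuffle control); directional disambiguation with 30 cells
per population; and a 10-minute six-neuron fixture for the end-to-end
determinism check.

## Known limitations

* The GMM segmentation assumes roughly Gaussian field shapes; crescent or
  boundary-hugging fields may be split or trimmed (the overrides file is
  the escape hatch, as interactive curation would be).
* Stability and Rayleigh tests lose power below ~20 events per context;
  the 10-event session floor keeps cells in the analysis that short
  sessions cannot reliably classify.
* Chance level of the standard decoding protocol depends on row balance,
  and the random-row split inflates absolute accuracies via duplicated
  window rows; between-condition comparisons under an identical protocol
  remain meaningful, but absolute accuracies should be read with the
  blocked variant in mind.
* The synthetic trajectory reproduces coverage and speed statistics, not
  the kinematics of real mice; directional-occupancy structure near walls
  is qualitatively, not quantitatively, matched.
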