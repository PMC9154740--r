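---
title: "Quantifying persistent behavioral states from frame-classified ethograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying persistent behavioral states from frame-classified ethograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethopersist)
```

## The problem

Female *Aedes aegypti* mosquitoes hunt humans by integrating brief sensory
cues — a plume of CO2, a pulse of skin-like heat — into a motivational state
that outlasts the cue by many minutes. In the assay this package models,
individual mosquitoes are filmed at 30 frames/s while stimuli are delivered
on programmable light and heat channels; frame classifiers turn each video
into an *ethogram*, a per-frame record of four boolean behavior flags
(groom, walk, probe, fly) plus a tracked x–y centroid. `ethopersist`
implements the downstream quantitative analysis:

1. stimulus-aligned population response curves and a nonparametric decay
   half-life,
2. a percent-additivity statistic for multimodal stimulation,
3. a fixed 38-parameter sliding-window feature vector,
4. low-dimensional embedding and clustering of windows into behavioral
   states (rest, global search, local search, engorge), and
5. a resampling-validated logistic classifier that predicts blood-feeding
   from pre-stimulus behavior.

A synthetic cohort generator with latent ground truth stands in for raw
video-derived data, so every stage can be validated against a known answer.

## Data model and conventions

Frames are 0-based and all frame spans are half-open `[start, end)`; times
are seconds as doubles. Behavior flags are stored *raw* (non-exclusive):
probing while walking is biologically real and several features use the
co-occurrence explicitly. Where a single category per frame is required
(bout counts, transition rates, state ethograms), flags are resolved by the
fixed precedence flying > probing > walking > grooming > no behavior
(`resolve_precedence()`).

A `cohort` bundles ethograms sharing one frame rate with a stimulus
timeline (named channels of non-overlapping pulses) and per-animal metadata
(sex, condition, engorged outcome). `align_to_stimulus()` re-indexes time
so `t = 0` is a chosen pulse onset; the shift is invertible and drops no
frames. On disk a cohort is a directory of per-animal CSVs
(`frame,time_s,groom,walk,probe,fly,x,y`) plus `meta.csv` and
`stimuli.json`; `write_cohort()` output is canonical, and a
read–write round trip is byte-identical.

Velocity is the centroid displacement over 100 ms (three frames at 30
frames/s) divided by the interval, in pixels/s. A sample requires both
interval endpoints, so a recording of `n` frames yields
`floor((n - 1) / 3)` samples; samples touching a tracking gap are `NA` and
are excluded from averages rather than imputed.

## Response curves and the decay half-life

`fraction_exhibiting()` computes, per time bin (default one frame), the
fraction of animals whose raw flag is on at any frame of the bin — the
"percent of individuals exhibiting" statistic; a per-animal time-fraction
variant is available behind the `per_animal_time` flag. The half-life of a
response (`half_life()`) is deliberately nonparametric:

* **baseline** — mean of the raw curve over the 2 min before onset;
* **maximum response** — the largest value of the 15 s sliding-window mean
  (`sliding_window_response()`) after onset, earliest window on ties;
* **t1/2** — the first window at or after the maximum whose value has
  fallen to or below halfway between maximum and baseline, in minutes.

The search starts at the maximum rather than at onset because the rising
phase crosses the halfway level too; starting at onset would return
t1/2 close to 0 for every response. A response that never exceeds baseline is
censored with reason `"no response"`; one that never falls back within the
record is `"right-censored"`. For an exponentially decaying response the
windowed mean rescales the amplitude but not the crossing time, so t1/2
equals the underlying exponential half-life exactly — this is what the
analytic fixture `make_decay_curve()` verifies, and why half-life recovery
on simulated cohorts is a fair parameter-recovery test.

## Percent additivity

For two stimuli A and B presented alone and together,
`percent_additivity()` divides each animal's combined-stimulus response
(mean probing over the first 15 s after onset, the same window used for the
prediction) by the sum of the two cohort-mean individual responses, times
100%: 0% is no response, 100% exactly additive, above 100% synergy. The
summary is the cohort median. Per-animal responses are not
baseline-subtracted (flag `percent_additivity` inputs yourself if desired);
time-resolved additivity series on a 500 ms grid are smoothed by a centered
9-bin (4.5 s) moving average with shrinking edges
(`smooth_additivity()`).

`make_additivity_scenario()` constructs cohorts in which the combined
response is, by construction and without noise, exactly the sum (or half,
or 1.5 times the sum) of the individual responses, so the 100%/50%/150%
identities are exact.

## The 38 window parameters

Each animal's track is split into 30 s windows at 10 s steps
(`make_windows()`; a final partial window is dropped) and each window is
summarized by exactly 38 named features (`feature_names()`), in four
families: 8 raw-flag proportions (the four behaviors, no behavior, probing
while walking, probing not walking, walking not probing); 5 bout counts of
the exclusive categories; 5 velocities (overall mean and mean during each
behavior, a velocity sample being labeled by its start frame); and 20
outgoing transition rates per second between the five exclusive categories
(transitions counted on consecutive-frame label changes, normalized by time
spent in the source category).

Minimum-exhibit cutoffs (0.04 flight, 0.2 walking or probing, 0.3
grooming) decide whether a behavior counts as exhibited in a window.
Because dropping windows would break the uniform grid the embedding needs,
a below-cutoff behavior instead has its *conditional* features zeroed —
bout count, velocity-during, and transition rates from **and into** it —
while its proportions are kept. Ethograms without a track get
zero velocities rather than missing values so feature vectors remain
embeddable without imputation.

## State inference

`embed_features()` z-scores each feature (dropping zero-variance columns
with a warning) and embeds windows in 2-D by exact t-SNE, implemented in
compiled code from the standard formulation: per-point Gaussian bandwidths
calibrated by binary search to a target perplexity, symmetrized and
normalized affinities, Student-t output kernel, gradient descent with
momentum, adaptive gains, and early exaggeration (learning rate 200, 1000
iterations by default). The perplexity follows the n/100 rule — the number
of windows divided by 100 — unless overridden; at unit-test scale
(hundreds of windows) the rule degenerates to perplexities near 2, so
small-fixture tests pass an explicit perplexity instead. The embedding is
deterministic given a seed (initial coordinates come from R's RNG) and was
cross-checked during development against an independent exact t-SNE on
identical standardized input.

`cluster_states()` segments the embedding. The default replaces the manual
cluster-circling of an interactive workflow with density-peak clustering:
local density rho from a Gaussian kernel whose width is the 2nd percentile
of pairwise distances, and for each point the distance delta to the nearest
denser point. Cluster centers are points that are simultaneously dense and
far from any denser point (delta more than 3 kernel widths, density above
the 10th percentile). Because a fixed threshold cannot distinguish a
spurious split of one cloud from two genuinely separate modes, candidate
centers are then merged by a valley test: the corridor between two centers
is sliced into eight segments, and if no slice is empty or sparse (the
density profile never falls below half the weaker center's density), the
two are the same mode. Low-density windows (bottom 5% by default) are left
`unassigned`, mirroring windows in which no state can be inferred. A
`kmeans` method and a `manual_polygons` override (point-in-polygon by ray
casting) expose the alternative workflows.

Clusters are then *named* by `name_states()` from absolute composition
archetypes — rest is still and grooms; global search flies and moves fast;
local search probes while walking; engorge probes nearly continuously while
motionless. Each cluster independently takes its best-matching archetype,
so an over-segmented state (the engorge state, for instance, often appears
as two sub-clusters) merges under one label; an explicit cluster-to-name
mapping can override the heuristic. `state_occupancy()` and
`state_ethograms()` summarize the labeled map as per-animal occupancy
fractions and per-state composition/transition/travel summaries, and
`state_robustness()` re-runs the pipeline at 10–60 s windows and reports
label agreement (adjusted Rand index) against the 30 s reference.

## Feeding prediction and resampling inference

`build_predictor_table()` extracts per-animal proportions of the four
behaviors over a pre-stimulus window (canonically the 2 min after the
light pulse, i.e. 2, 8 or 14 min before the heat pulse depending on the
inter-stimulus interval) plus the engorged outcome. The model
(`fit_and_score()`) is an L2-penalized logistic regression with
class-balanced weights `n / (2 n_class)`, fit by Newton/IRLS to the
penalized-likelihood optimum (relative tolerance 1e-8; the optimum was
cross-checked against an independent penalized solver). The penalty weight
is fixed at 1, the common default of liblinear-style solvers; note this
convention ties the effective regularization to the sample size, so
duplicating a dataset is equivalent to halving the penalty.

Performance is summarized as *balanced accuracy* at threshold 0.5, whose
chance level is 0.5 regardless of the fed/unfed imbalance. The observed
model, the 10,000 bootstrap refits (`bootstrap_performance()`, resampling
animals with replacement; single-class resamples redrawn) and the 10,000
outcome shuffles (`shuffle_null()`) are all scored *in sample* with the
same statistic, so the z test
`(observed - mean(null)) / sd(null)` (`significance()`, one-sided normal
upper tail, empirical percentile alongside) compares like with like: the
optimism of in-sample fitting inflates observed and null equally. The
separate leave-one-out cross-validation score is the overfitting check —
under the null it sits at 0.5 where the in-sample null median sits near
0.56 for four predictors and n = 150. A distribution-vs-distribution z
(bootstrap mean vs null, pooled spread) is reported as `z_boot` for
comparison. Calibration of the whole procedure is itself under test: over
200 generated null cohorts (outcome independent of behavior) the rejection
rate at alpha = 0.05 stays within [0.02, 0.09], and a +0.15 shift in fed
animals' probe proportion at n = 150 is detected with power above 0.8.

## The synthetic generator

`simulate_cohort()` draws cohorts from a semi-Markov latent-state model.
Each animal rests until a trigger pulse; a light (fictive CO2) pulse sends
it with probability 0.9 into a global-search state whose dwell is
exponential with half-life 234 s (3.9 min — the persistent state), after
which it either relaxes to rest or passes through a local-search state; a
heat pulse triggers a brief local search (half-life 24 s, or 0.4 min).
Within a state, behavior is emitted as alternating bouts: the bout type is
drawn so that stationary per-frame time fractions equal the state's
emission probabilities (the draw probability is the emission probability
divided by the mean bout length), and bout durations are geometric with
behavior-specific means — a two-level process chosen so bout counts and
transition rates are meaningful at 30 frames/s. Tracks are random walks
with per-behavior speeds. Engorgement is drawn per animal from a logistic
model on local-search occupancy during the 2 min before the heat pulse,
and engorged animals enter an absorbing engorge state at the heat pulse
offset. All randomness comes from one stream seeded from the
configuration, so cohorts are bit-reproducible.

Defaults (`default_config()`) encode the assay conditions: 70 animals,
20 min trials at 30 frames/s, 5 s pulses (light at 300 s, heat at 900 s).
The emission profiles are deliberately extreme because classified behavior
in this assay is: a resting mosquito is essentially still apart from
grooming bursts; global search is dominated by flight and fast walking;
local search by sustained surface probing; an engorging mosquito probes
nearly continuously while motionless. An early draft of these defaults
used milder, more mixed profiles; diagnostic runs showed they produced
latent states that a supervised classifier could separate but that did not
form distinct density modes — unlike the clearly separated state clusters
the analysis is premised on — and, worse, placed mean behavior proportions
on top of the exhibit cutoffs so that windows of one state bifurcated into
two discrete feature regimes. The profiles were therefore revised once to
the present values, which keep every state firmly on one side of every
cutoff; they are a modeling choice, not estimates from data.

What the generator does *not* emulate: classifier noise (flags are
emitted, not inferred), tracking artifacts beyond missing samples, wall
effects or arena geometry in the random-walk tracks, diel/satiety drift in
baseline behavior, and between-animal heterogeneity in emission profiles.
Passing recovery tests therefore demonstrates correctness of the analysis
under the model's assumptions, not performance on real video-derived data.

## Numerical choices and problem sizes

* Half-life grids: response curves are binned per frame; the sliding
  window is 450 frames; crossings are detected with a 1e-12 slack so exact
  halfway values count as crossed.
* Additivity fixtures use response fractions that are whole numbers of
  frames, making the 100%/50%/150% identities exact in floating point.
* t-SNE: exact O(n^2) gradients; the validation suite embeds a seeded
  3000-window subsample of the default cohort (8260 windows), a scale at
  which the exact method runs in about a minute and a half; the full
  cohort embeds in under ten minutes if wanted. Perplexity is clamped to
  [2, (n-1)/3].
* Density peaks: kernel width = 2nd percentile of pairwise distances;
  center criterion delta > 3 kernel widths; valley test at half the weaker
  center's density over an 8-slice corridor profile; at most 12 auto
  clusters before naming merges them.
* Resampling suite sizes: the calibration test uses 200 null cohorts with
  500 shuffles each and 50 powered cohorts with 1000 shuffles (scaled down
  from the 10,000 used for a single real analysis); CLI defaults follow
  the 10,000-draw convention.
* Ridge IRLS: Newton steps with a 1e-8 relative deviance tolerance and a
  tiny Levenberg fallback if the Hessian is singular.

## Known limitations

* The 38-feature roster is one defensible reconstruction of the listed
  feature families; the exact historical itemization is not published, so
  order-sensitive downstream code should rely on `feature_names()`.
* Cutoff zeroing is interpretive ("excluded from further analysis"); both
  the implementation and its independent test oracle implement the same
  reading, and the cutoffs remain user-settable.
* The half-life has no confidence interval; it is a point statistic on the
  windowed curve.
* The naming heuristic assumes the four canonical states; exotic cohorts
  (e.g. males with no engorge state) should pass an explicit `labels`
  mapping.
* With fewer than ~200 windows the n/100 perplexity rule is degenerate and
  an explicit perplexity must be chosen.

## A worked run

```{r, eval = FALSE}
cfg <- default_config()
cfg$n_animals <- 20L
sim <- simulate_cohort(cfg)

co <- align_to_stimulus(sim$cohort, "light", 1)
curve <- fraction_exhibiting(co, "probe")
half_life(curve)

sc <- make_additivity_scenario("additive")
cohort_additivity(sc)$median_pct

feats <- window_features(sim$cohort)
Y <- embed_features(feats, seed = 1)
states <- name_states(cluster_states(Y), feats)

tab <- build_predictor_table(sim$cohort, window = c(0, 120))
feeding_report(tab, B = 1000, S = 1000, seed = 1)
```
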