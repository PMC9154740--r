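# ethopersist

Quantitative analysis of **persistent behavioral states** in
frame-classified animal ethograms, built around opto-thermal stimulation
assays of mosquito host seeking. The input is one ethogram per animal —
per-frame boolean flags for groom, walk, probe and fly at 30 frames/s,
with an optional x–y centroid track — plus a stimulus timeline (light and
heat channels) and per-animal outcomes (engorged or not). The package is
aimed at researchers who already have classified behavior streams (e.g.
from JAABA-style classifiers downstream of video tracking) and need the
statistics that turn them into biology.

## What it computes

**Response decay half-life.** For a stimulus-aligned population response
curve f(t) (fraction of individuals exhibiting a behavior), with baseline
b = mean f over the 2 min before onset and maximum response M = max of the
15 s sliding-window mean w(t) after onset,

    t1/2 = min { t >= argmax w : w(t) <= b + (M - b) / 2 },

reported in minutes, censored when the response never exceeds baseline or
never falls back. For an exponential decay this recovers the true
half-life exactly, because the sliding window rescales amplitude but not
the crossing time.

**Percent additivity** of two stimuli A and B:
`100 × r_AB / (mean r_A + mean r_B)` per animal, median over the cohort —
0% is no response, 100% exactly additive, >100% synergy.

**Behavioral-state inference.** Each track is cut into 30 s windows at
10 s steps and summarized by a fixed vector of 38 parameters (behavior
proportions including probe∧walk co-occurrence, bout counts, velocities,
and 20 per-second transition rates between precedence-resolved
categories, with minimum-exhibit cutoffs). Windows are embedded in 2-D by
exact t-SNE (perplexity = n/100) and segmented by density-peak clustering
with a density-valley merge test; clusters are named rest / global_search
/ local_search / engorge from composition archetypes.

**Feeding prediction.** A class-balanced L2-penalized logistic regression
predicts engorgement from the four behavior proportions in a pre-stimulus
window, validated by leave-one-out cross-validation, 10,000 bootstrap
refits, and a 10,000-permutation shuffle null with a one-sided z test.

**Synthetic cohorts.** A semi-Markov generator emits ethograms from
latent states with exponential persistence (default probing half-life
234 s after a 5 s light pulse), state-dependent bout-structured behavior,
random-walk tracks, and a logistic feeding model — with the latent traces
returned as ground truth, so every estimator above is validated by
parameter recovery.

## Worked example

```r
library(ethopersist)

## a 70-animal, 20-min cohort receiving a single 5 s light pulse at 300 s
cfg <- default_config()
cfg$seed <- 1L
cfg$stimuli <- stimulus_series(list(
  light = data.frame(onset_s = 300, offset_s = 305, magnitude = 1)))
sim <- simulate_cohort(cfg)

co <- align_to_stimulus(sim$cohort, "light", 1)
half_life(fraction_exhibiting(co, "probe"))
#> <half_life> t1/2 = 3.48 min (baseline 0.006, max 0.138 at 123.233 s)
```

Before the pulse, 0.6% of animals are probing at any instant; the pulse
drives a response peaking at 13.8% of individuals, and the windowed
response takes 3.5 min to fall halfway back — the persistent state, on
the scale of the 234 s latent half-life the cohort was generated with.

```r
## exactly additive two-stimulus construction -> 100% by definition
cohort_additivity(make_additivity_scenario("additive"))$median_pct
#> [1] 100

## predict engorgement from the 2 min of behavior before the heat pulse
cfg2 <- default_config(); cfg2$seed <- 2L; cfg2$n_animals <- 150L
sim2 <- simulate_cohort(cfg2)
tab <- build_predictor_table(sim2$cohort, window = c(-120, 0),
                             channel = "heat")
rep <- feeding_report(tab, B = 1000, S = 1000, seed = 1)
round(c(observed = rep$observed, loo = rep$loo, z = rep$z, p = rep$p), 3)
#> observed      loo        z        p
#>    0.656    0.597    1.920    0.027
round(rep$coefficients, 2)
#> (Intercept)       groom        walk       probe         fly
#>       -0.31       -0.71        1.47        1.61        0.15
```

The model's balanced accuracy of 0.656 sits at the 97th percentile of the
shuffle null (p = 0.027): animals probing and walking — searching locally
— in the two minutes *before* the blood-meal cue are the ones that go on
to feed, which is exactly the structure the generator's feeding model
encodes.

A command-line front end mirrors the R API
(`inst/cli/ethopersist`): `validate`, `simulate`, `halflife`,
`additivity`, `features`, `states`, `predict`, each deterministic under
`--seed`.

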