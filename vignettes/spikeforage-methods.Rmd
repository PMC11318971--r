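---
title: "Methods: event-aligned analysis of foraging-under-threat recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-aligned analysis of foraging-under-threat recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `spikeforage`, the
default parameters and the reasoning for each, the realism and limits of the
synthetic generator, and the numerical choices that matter for
reproducibility. No empirical result is reported here beyond what the
package's test suite and `scripts/acceptance.R` compute on synthetic data.

## The experiment the package models

A rat shuttles between a safe nest and a foraging arena to retrieve food
pellets while, in a *threat* phase, a robot predator surges at it when it
approaches the pellet. Single units are recorded in dPAG and BLA across three
phases (*pre*, *threat*, *post*), with optional dPAG electrical stimulation
sessions. The package's analyses are:

1. **PETH**: peri-event time histograms of each unit around phase-specific
   alignment events (pellet procurement in pre/post, robot activation in
   threat), z-scored against a pre-event baseline.
2. **Classification**: a per-unit label (`robot`, `pellet`, `both`,
   `inhibited`, `none`) from excitation in the early post-event window of
   each phase, plus a motor confound screen correlating firing rate with
   locomotion speed.
3. **Synchrony**: shift-predictor-corrected cross-correlograms between
   simultaneously recorded pairs in 2-s post-event epochs, with a
   significance test on the 0–100 ms lag window.
4. **Behavior**: per-trial kinematics (outbound latency, approach speed) and
   pellet success rates from tracking and trial tables.

## PETH model and defaults

`compute_peth(times, events, window = c(-5, 5), bin_width = 0.1,
baseline = c(-5, 0))` counts spikes into half-open bins
`[left, left + 0.1)` on a shared edge grid anchored at the event. The
trial-averaged rate is z-scored using the mean and *sample* SD of the 50
baseline bins. Defaults and rationale:

* **Window ±5 s, 0.1 s bins** — long enough to estimate a stable baseline
  from 50 bins, fine enough to resolve onset latencies of tens to hundreds
  of milliseconds.
* **Baseline = the full 5 s pre-event window** — the event alignments are
  spaced more than 10 s apart, so baselines never overlap a neighbouring
  response.
* **Zero baseline SD ⇒ non-classifiable** — a silent or perfectly regular
  baseline gives no scale for z; such units are flagged (`classifiable =
  FALSE`) rather than forced through with a pseudo-SD.

Binning uses `findInterval` on the explicit edge vector, so a spike exactly
at the event time lands in the first post-event bin and bin membership is
identical across machines (no accumulation of `seq()` floating-point drift).

## Classification rules

A phase is *activated* when any of the first `n_test_bins = 5` post-event
bins (0–500 ms) has z > `z_threshold = 3`. Labels:

* `both` — activated in threat *and* in pre or post;
* `pellet` — activated in pre or post only;
* `robot` — activated in threat only; under the default
  `exclusivity = "both"` this requires no activation in *either* pre or
  post. The alternative `exclusivity = "pre_only"` only requires silence in
  pre; it is provided because either reading is defensible, and the choice
  is surfaced as a config parameter rather than hidden.
* `inhibited` — any of the first 5 post-event bins with z < −3 and no
  activation anywhere;
* `none` — otherwise.

Latency is the left edge of the first crossing bin; with 0.1 s bins it is
quantised to the bin grid, which is the resolution limit of this design, not
a bug. Peak z and maximum rate over 0–500 ms are reported alongside.

**Calibration caveat.** With Poisson spike counts, the per-bin tail
probability of z > 3 is ≈ 0.0055 at typical baseline rates — about four
times the Gaussian 0.00135 — because the z statistic is built from skewed,
discrete counts with an estimated SD. Across 3 phases × 5 test bins this
puts the fraction of homogeneous-Poisson units labelled something other than
`none` at roughly 5%, not the ≤ 2% a Gaussian intuition would suggest. The
test suite measures this honestly rather than adjusting the threshold; users
who need a tighter family-wise rate should raise `z_threshold` explicitly.

The speed screen (`speed_rate_correlation`) bins the session into 1-s bins,
computes the Pearson correlation between speed and spike count, and flags
`significant` at `alpha = 0.05`. It is a confound *screen*, not a causal
test.

## Synchrony

`cross_correlogram(ref, target, events)` restricts both trains to half-open
2-s epochs `[event, event + 2)`, histograms target-minus-reference lags into
10 ms bins over ±0.5 s, and corrects by a **shift predictor**: the mean
cross-correlogram over `n_shuffles = 100` fixed-point-free permutations
(derangements) of trial identities. Derangements guarantee no trial is
paired with itself, so the predictor estimates the event-locked (stimulus)
component only; with exactly 2 usable events the single derangement is the
deterministic swap and the predictor SD is zero. Per-trial histograms are
precomputed once, so shuffles are O(trials²) table sums, not rescans of the
spikes.

Two significance nulls are implemented via `cc_null`:

* `"shuffle"` (default): z = corrected / predictor SD per bin.
* `"flank"`: z = (corrected − mean(flank)) / sd(flank), where the flank is
  every corrected bin *outside* the 0–100 ms test window.

**Calibration caveat.** The shuffle SD measures only between-permutation
variability of the fixed observed spikes and therefore *underestimates* the
sampling SD of the corrected correlogram — the raw histogram's own Poisson
variance does not enter it. On independent 5 Hz pairs with 10 events, the
shuffle null flags roughly 12–20% of pairs at z > 3 somewhere in the ten
test bins; the flank null, which absorbs the full sampling variance, brings
this to roughly 7%. Neither is an exact 3%-level test (ten family-wise bins
of skewed counts), but the flank null is the better-calibrated choice when
the question is "is this pair synchronized at all" rather than "is the peak
large relative to the event-locked component". The shuffle null remains the
default because the corrected-over-predictor-SD statistic is the
conventional construction this analysis mirrors; both are exposed and the
choice is recorded in the run's `config.yaml`.

AUC summaries integrate the corrected correlogram over 0–100, 0–50 and
50–100 ms (sum × bin width). With `auc_per_event = TRUE` (default) they are
divided by the number of events so sessions with different trial counts are
comparable. A pair enters the analysis only if both units fire at
≥ `min_rate = 0.1` Hz over the full session; `synchronized` means
significant in the post-robot-surge epoch.

## Behavior

`session_behavior` computes, per trial: outbound latency from gate opening
to arena entry, time to the pellet zone, approach speed, flee detection
(heading reversal after the surge), and outcome. Trials are excluded when
the inter-trial gap is under 10 s (strictly), and kinematics are capped at
180 s to bound runaway trials; both rules are applied before any unit-level
analysis via `apply_trial_exclusions`. `success_rate` reports per-phase
pellet success over non-excluded trials.

## Synthetic generator

`simulate_session(synthetic_config(...))` builds a full session with ground
truth:

* **Schedules** (`make_event_schedule`): per-phase trial counts with ITIs
  (mean 30 s, floor 15 s) that keep alignment events > 10 s apart, so PETH
  baselines are clean by construction.
* **Units** (`make_unit`): inhomogeneous Poisson trains sampled by
  *thinning* — candidates at the rate ceiling, kept with probability
  rate(t)/ceiling. Response profiles add an amplitude on top of a base rate
  with `boxcar` or `exp_decay` (τ = duration/3) kernels, gated by a phase
  mask; speed coupling multiplies the rate by a speed-dependent modifier.
* **Pairs** (`make_pair`): *joint selection* — a mother train is sampled and
  each mother spike is copied into both daughters with probability
  `p_share`, the target copy delayed by `lag` plus Gaussian jitter, only
  inside masked epochs. The expected excess coincidence mass is analytic
  (`p_share × rate × active_time × bin_width`), which the tests exploit.
* **Tracking** (`make_speed_trace`): piecewise-linear position keypoints
  through nest/gate/pellet waypoints per trial, sampled uniformly.
* All draws flow from one root seed through a counter-based
  `derive_seed(seed, k)` scheme (seeds kept below 2³¹), so any component is
  reproducible in isolation and the whole dataset is byte-identical across
  runs (`make_dataset` writes TSVs with stable formatting).
* Spike times are snapped away from sub-1/32000 s gaps to respect the
  acquisition resolution the readers enforce.

**Realism and limits.** The generator is Poisson: no refractoriness,
bursting, or slow non-stationarities, so real recordings will have wider
count dispersion than the synthetic calibration predicts. Coupling is
feed-forward copy-with-delay, not a recurrent circuit. Tracking is
kinematically plausible but noiseless. These choices make every headline
quantity analytically checkable, which is what the test suite needs; they
are not a claim that the generator reproduces full biological variability.

## Pipeline and reproducibility

`run_config()` + `run_pipeline(config, out_dir)` run data loading (or
simulation), exclusions, the rate filter, classification, synchrony, and
behavior, writing TSV tables plus `config.yaml`, `summary.txt` and
`log.txt` (seed, config digest, stage timings). An `INCOMPLETE` marker file
exists while the run is in flight and is removed on success; a failed stage
aborts with the stage named. `read_run_config()` round-trips the YAML so a
run can be reproduced byte-for-byte from its own artifacts. A thin CLI
(`inst/scripts/forage-cli.R`) wraps the same functions with exit codes
0/1/2 for ok / usage-or-config error / runtime failure.

`scripts/acceptance.R --seed <int> --out <path>` runs the main computations
(classifier calibration and recovery, both synchrony nulls, coupled-pair
recovery against the analytic coincidence mass, the speed screen, and a
full pipeline demo) and writes the quantities as JSON. All of its
randomness derives from `--seed`.

## Limitations

* Latency resolution is one PETH bin (0.1 s).
* The z > 3 rule on Poisson counts is anti-conservative (~5% type-I for the
  classifier; see above), and the shuffle synchrony null more so; both are
  measured, documented, and left for the user to tighten via `z_threshold`
  or `cc_null = "flank"` rather than silently re-tuned.
* The shift predictor needs ≥ 2 usable events; epochs with fewer are
  dropped with a warning.
* Stimulation-session analysis reuses the threat-alignment machinery; no
  artifact removal is modelled.
* No spike-sorting quality metrics are ingested; units are taken as given.
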