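---
title: "Quantifying long-range axonal transport with axontrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying long-range axonal transport with axontrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axontrack)
library(dplyr)
```

`axontrack` quantifies single-particle transport along axons grown through
microfluidic grooves. This vignette describes the models and conventions
the package implements, the parameters that matter and why their defaults
are what they are, what the synthetic generators emulate, and the
numerical choices made where the design was genuinely open.

## Coordinate and unit conventions

One convention is used everywhere: `x = 0` at the somatodendritic end of
the groove, `x = groove_length` (default 500 µm) at the axon tip.
Retrograde motion — toward the cell body — therefore has `dx/dt < 0`.
Frames are 0-based, times in seconds, positions in micrometres,
intensities in camera arbitrary units (AU). File readers normalize units
at the boundary; nothing downstream converts.

## Photobleaching step counting

A diffraction-limited spot containing $n$ labeled fluorophores loses
intensity in discrete steps of roughly 26 AU as fluorophores bleach.
Counting steps therefore bounds the number of tagged molecules: a motor
carrying two tagged heavy chains yields predominantly two steps per
molecule, a complex with a single tagged subunit one.

`fit_steps()` fits a piecewise-constant model to a trace by exact dynamic
programming: for each candidate step count $k \le$ `max_steps` it finds
the change-point placement minimizing the residual sum of squares subject
to a minimum plateau length, then selects $k$ by minimizing
$\mathrm{RSS}(k) + \lambda k$. Because the per-$k$ optimization is exact,
the fit attains the same residual as exhaustive enumeration of
change-point placements — a property the test suite checks directly
against a brute-force oracle.

Key parameters:

- **Penalty $\lambda$** (default `3 * sigma^2 * log(n)`, $\sigma$ from the
  median absolute deviation of first differences divided by $\sqrt 2$).
  The factor 3 sits between the one-parameter BIC (2) and the
  two-parameters-per-step convention (4): each step adds a free plateau
  level plus a grid-constrained location. It was calibrated once on
  synthetic traces at the generator's default noise (6 AU on 26 AU
  steps): a factor of 2 admits occasional spurious steps, a factor of 4
  sacrifices exact-count recovery. Step count is non-increasing in
  $\lambda$ on a fixed trace.
- **Minimum segment length** (default 5 frames at 30 Hz, ~0.17 s):
  rejects single-frame blinking artifacts. Two fluorophores bleaching
  within this window merge into one double-height step — an intrinsic
  resolution limit of step counting, not of this implementation.
- **Step sign** (default decreases only): bleaching can only lose
  intensity, so fitted change points whose step is non-negative are
  merged away. An option retains increases (blinking back), but such
  steps are excluded from population step-size statistics.
- **Background**: a user-supplied off-spot estimate takes precedence;
  absent that, the post-bleach tail (last fitted level) is used.

`summarize_steps()` pools fits into the step-count histogram, the modal
count (ties broken toward the smaller count, so a 1/2 tie reports 1 —
deterministic and conservative about stoichiometry), and pooled
absolute step sizes. `implied_fluorophores()` converts a
background-subtracted spot intensity $I$ into
$\max(1, \lfloor I / 26 \rfloor)$ fluorophores for $I > 0$; under this
reading a 200 AU ceiling corresponds to seven fluorophores.

## Track kinetics

Tracks arrive as per-spot tables (TrackMate-dialect CSV via
`read_tracks()`, or straight from the simulator). The conventions follow
the analysis practice of the imaging studies this package serves:

- **Speed** (default `net`): absolute net displacement over track
  duration — speed "from the beginning to the end of the track",
  including paused time. A `path` option (summed $|\Delta x|$ over
  duration) is computed alongside, and both are reported per track; for
  near-unidirectional runs the two nearly coincide. Net speed never
  exceeds path speed.
- **Motile filter** (default 10 µm): only tracks whose net displacement
  reaches 10 µm enter population statistics; the filter is applied to net
  displacement to match run-length semantics. Sub-threshold tracks are
  labeled stationary.
- **Instantaneous velocity** (default 3-frame central difference):
  $v_i = (x_{i+w} - x_{i-w}) / (t_{i+w} - t_{i-w})$, one-sided at track
  ends. At 2 Hz this is a 1 s baseline; unsmoothed frame-to-frame
  velocities would carry noise comparable to the pause threshold.
- **Pauses** (threshold 0.1 µm/s, minimum duration 1 s): maximal runs of
  frames below threshold. Single-frame interruptions of a run are merged
  away — the same rationale as the minimum duration, since one-frame
  crossings at this sampling rate are noise. An event's duration is its
  frame count times the frame interval, capped at the track span, which
  makes a noiseless 10 s creep between two fast runs score 9.5–10 s and
  keeps total paused time within the track duration.

Population summaries report means with SEM both over tracks and over
biological replicates; figure-level error bars in this field are SEM over
replicates, but the per-track spread is what a power calculation needs,
so both are labeled explicitly. `event_frequency()` counts qualifying
tracks per movie and divides by movie minutes — per movie, not per axon
or per micrometre, matching how per-video counts are reported.
`first_arrival_time()` returns the first frame time of the earliest
qualifying track per movie, in minutes, with an explicit "not observed"
status when no track qualifies.

## Two-channel colocalization

The matching criterion is deliberately simple and fully exposed, because
published figures rarely state one: a candidate pair needs at least
`min_overlap_frames = 3` common frames, and matches when at least
`min_overlap_fraction = 0.5` of its overlapping frames sit closer than
`max_separation = 0.5` µm — sub-diffraction-scale proximity sustained
over most of the co-visible interval. Assignment is one-to-one, greedy by
ascending mean separation with ties broken by track id: deterministic,
and at realistic track densities conflicts are rare enough that greedy
and globally optimal assignment coincide. Percentages are reported
relative to both channels (the two channels can hold very different track
counts, so both references are informative), and
$\mathrm{pct}(A) \cdot n_A = \mathrm{pct}(B) \cdot n_B =
100\, n_\mathrm{matched}$ holds by construction.

## First-arrival transport models

Two mechanisms are contrasted for a motor labeled at the axon tip at
$t = 0$:

- **Stable binding**: the motor crosses the groove in one trip,
  $T = L / (\bar v\,(1 - p_\mathrm{pause}))$. At $L = 500$ µm and
  $\bar v = 1.76$ µm/s this is 284 s ≈ 4.73 min, i.e. under five
  minutes. The headline bound is evaluated at $p_\mathrm{pause} = 0$
  (the arithmetic behind the five-minute expectation ignores pausing);
  pause-adjusted values are available through the same closed form.
- **Motor exchange**: the labeled motor advances in exponential runs of
  mean $\ell$ (default 2 µm, the scale of reported short-range
  movements), then waits an exponential $\tau$ (default 5 s) to rebind,
  stationary while unbound. The closed-form mean used is
  $T = L/v + (L/\ell - 1)\tau$, the large-$L/\ell$ expression; the exact
  renewal mean of the simulated process is $L/v + (L/\ell)\tau$, one wait
  larger, a difference below 0.5% at the defaults. Run lengths are
  exponential (memoryless, single-parameter, the single-molecule
  convention); diffusion during waits is deliberately omitted because it
  would add parameters the experiments do not constrain.

`compare_models()` reports both means and their ratio (~5.4 at the
defaults), and classifies a user-supplied observed arrival time as
consistent with the model whose mean is nearer on a log scale — the two
predictions differ multiplicatively, so log distance is the natural
metric; exact ties (e.g. $\tau = 0$) report `"both"`.

## Replicate-level statistics

All between-group tests operate on biological-replicate means, never on
pooled tracks: tracks within a differentiation are correlated, and the
replicate is the independent unit. `omnibus_test()` then gates on
normality jointly: Shapiro–Wilk per group at $\alpha = 0.05$; if every
group passes, Student's $t$ (two groups) or one-way ANOVA with Tukey's
post hoc; if any group fails — or is too small to test (fewer than three
values) or has zero variance — the whole family switches to
Kruskal–Wallis with Dunn's post hoc. The gate is all-or-nothing because
mixing parametric and rank-based pairwise results within one family is
not interpretable. Dunn $z$ statistics use pooled ranks with tie
correction; the multiplicity adjustment is Holm by default with a `none`
option, and raw p values are always reported alongside, since published
legends rarely state whether post hoc p values were adjusted. Identical
constant groups return a `degenerate-variance` status rather than an
error. The suite verifies the gated pipeline's type-I error stays within
[0.03, 0.07] at nominal 0.05 under the null.

## What the synthetic generators emulate

`simulate_tracks()` draws, per track, a direction (retrograde /
anterograde / stationary mix), a run speed from a normal truncated to
[0.3, 5.0] µm/s (defaults: mean 1.76, sd 0.5), and motion alternating
exponential runs (pause entry rate 0.05 s⁻¹) with exponential pauses
(mean 4 s) — a two-state continuous-time Markov process, the minimal
model reproducing run/pause statistics without inventing richer
dynamics. Tracks are observed at 2 Hz inside a [0, 110] µm window of a
500 µm groove, with Gaussian localization noise, and terminate after an
exponential visible path length (mean 35 µm) emulating particles
drifting out of focus; termination is censoring, not detachment, and is
flagged in the ground truth. With `label_onset = TRUE` motile particles
depart the tip at $t = 0$, reproducing the first-arrival experiment.

Two defaults deserve comment:

- **Localization noise 0.03 µm.** Neither the imaging regime's
  localization precision nor its defocus statistics are published
  quantities; both defaults are explicit stand-ins and configurable. The
  value 0.03 µm is typical near-single-molecule HILO precision
  (20–40 nm) and keeps the 3-frame central-difference velocity noise
  (~0.042 µm/s) comfortably below the 0.1 µm/s pause threshold, so a
  stationary particle scores below threshold in ≥ 95% of frames. At
  0.05 µm that fraction drops to ~85% and threshold-based pause
  detection fragments — an internally inconsistent regime for this
  analysis convention.
- **Two pause ground truths.** The truth table records both the physical
  continuous-time paused fraction and the pause observable (thresholded
  central-difference velocity at the default settings) evaluated on the
  noise-free trajectory. Parameter-recovery tests compare the estimator
  to the latter: the pause observable is definitionally
  threshold-and-window dependent — boundary frames and sub-minimum
  pauses are excluded by construction — so even a perfect noise-free
  detector reports ~1.5 percentage points below the physical fraction at
  the default motion parameters. Conflating the two would misattribute a
  definitional offset to estimator error.

`simulate_bleach_traces()` composes each spot from a molecule count drawn
from a configurable probability table, `copies_per_molecule` taggable
subunits each labeled with probability `labeling_efficiency` (default
0.9), per-fluorophore step intensities (mean 26 AU, sd 4) held until
exponential bleaching times (rate 0.25 s⁻¹ over 20 s at 30 Hz, so
essentially all fluorophores bleach within the trace), plus additive
Gaussian noise (sd 6 AU). Noise is additive Gaussian only — no Poisson
shot-noise term — so oracles stay tractable; the sd is configurable.
Fluorophore counts per spot follow the analytic mixture of binomials
(`fluorophore_count_pmf()`), and odd counts arise from partial labeling
even with two copies per molecule.

`simulate_dual_channel()` gives a configured fraction of channel-A tracks
a channel-B partner re-observed with independent localization noise; the
pair count is set by the number of generated A tracks, so a configured
10% of 500 tracks yields exactly 50 ground-truth pairs.
`render_kymograph()` rasterizes tracks into the standard time-by-position
image with a Gaussian profile per spot.

What the generators do **not** emulate: spot detection and linking (the
pipeline consumes track tables, so detection failures, identity swaps and
gap closing are out of scope), shot noise and background structure,
three-dimensional geometry, bidirectional switching within a track, and
photophysics beyond single-exponential bleaching. Passing recovery tests
therefore demonstrates correctness of the quantification stack under the
stated statistical structure, not robustness to tracking artifacts in
real videos.

All generators are deterministic given their seed; a single top-level
seed drives per-operation sub-streams derived arithmetically, so any
stage can be reproduced in isolation.

## Problem sizes and numerical notes

The shipped tests and the acceptance script use 300 traces per
stoichiometry condition, 500 tracks for kinetics recovery, 300 A-tracks
for colocalization recovery, 200 simulated particles per arrival model
and 1,000 null replicates for the statistics calibration — sizes at which
every Monte-Carlo criterion (3-SE, binomial 95% CI, 2-point pause band)
is comfortably resolved while the whole suite runs in a few minutes.
Degenerate inputs are handled explicitly: constant traces fit zero steps,
zero-duration tracks error, an all-filtered population returns an empty
status, and an empty track set reports "not observed" arrival. Emitted
noisy positions are clamped to the imaging window so no observed position
ever lies outside it.

## Known limitations

- Step counting cannot separate fluorophores bleaching within one
  minimum-segment window; stoichiometry conclusions are modal, not
  per-spot guarantees.
- The exchange model's waiting process (stationary, exponential) is a
  modeling choice; published observations constrain the run length scale
  but not the wait mechanism.
- Whether published "average speed" includes paused frames is not stated
  in figure legends; both conventions are computed, and which matches a
  given figure exactly cannot be determined without the underlying raw
  data.
- Direction classification is by sign of net displacement only;
  genuinely bidirectional cargoes are beyond its scope.
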