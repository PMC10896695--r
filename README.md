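# axontrack

Quantification of long-range axonal transport from near-single-molecule
imaging data.

`axontrack` is an R toolkit for labs measuring how molecular motors — the
dynein transport machinery in particular — move along axons grown through
microfluidic grooves. Neurons in these devices extend axons through a
~500 µm channel; labeling one compartment and imaging the other turns the
groove into a natural experiment on transport distance. The package
implements the full quantification stack such experiments need:

- **Photobleaching step counting** (`fit_steps()`, `summarize_steps()`):
  penalized least-squares change-point fitting of 30 Hz spot intensity
  traces. A spot containing *n* labeled fluorophores loses ~26 AU per
  bleaching event, so the step count bounds the number of tagged molecules
  (two tagged copies per dynein motor, one per dynactin complex).
- **Track kinetics** (`track_summaries()`, `detect_pauses()`,
  `event_frequency()`, `first_arrival_time()`): per-particle speed
  (net displacement over duration), run length, direction, pause events
  (instantaneous speed < 0.1 µm/s), percent pausing, motile-event
  frequency and first-arrival times from TrackMate-style track exports
  sampled at 2 Hz.
- **Two-channel colocalization** (`match_tracks()`,
  `summarize_colocalization()`): one-to-one matching of tracks imaged
  simultaneously in two channels by sustained sub-micrometre proximity.
- **First-passage transport models** (`stable_arrival()`,
  `exchange_arrival()`, `compare_models()`): closed-form and simulated
  first-arrival times contrasting a motor stably bound to its cargo,
  `T = L / (v (1 - p_pause))`, with a motor exchanged after short runs,
  `T = L/v + (L/ℓ - 1) τ` for runs of mean length ℓ and rebinding waits of
  mean τ.
- **Replicate-level statistics** (`omnibus_test()`, `dunn_posthoc()`):
  the field's convention of testing biological-replicate means, gated by
  Shapiro–Wilk normality into either one-way ANOVA + Tukey or
  Kruskal–Wallis + Dunn.
- **Synthetic data generators** (`simulate_tracks()`,
  `simulate_bleach_traces()`, `simulate_dual_channel()`,
  `render_kymograph()`): seeded simulators of tracks, bleaching traces,
  dual-channel data and kymographs with full ground truth, so every stage
  of the pipeline is testable without any raw videos.

Everything is tidyverse-native: functions take data frames first, return
tibbles, and fitted objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

How long should the first labeled dynein take to cross a 500 µm groove if
it stays bound to its cargo, versus being exchanged every couple of
micrometres?

```r
library(axontrack)

cmp <- compare_models(
  arrival_config(groove_length = 500, speed = 1.76,
                 run_length_mean = 2, rebind_wait_mean = 5),
  observed_min = 3.49
)
cmp$table
#> # A tibble: 2 × 2
#>   model    mean_min
#>   <chr>       <dbl>
#> 1 stable       4.73
#> 2 exchange    25.5
cmp$ratio
#> [1] 5.3824
cmp$consistent_with
#> [1] "stable"
```

A stably bound motor at the mean retrograde speed of 1.76 µm/s arrives in
4.73 min — under five minutes — while the exchange model predicts
~25.5 min, more than five times slower. An observed arrival of 3.49 min is
therefore consistent only with stable binding.

Counting tagged molecules from bleaching traces:

```r
sim <- simulate_bleach_traces(sim_trace_config(
  n_traces = 300, copies_per_molecule = 2, seed = 11
))
pop <- summarize_steps(fit_steps_all(sim$traces))
pop
#> <step_population> 300 spots, modal step count 2, |step| 26.26 +/- 6.91 AU
```

With two tagged copies per motor the modal step count is 2; rerunning with
`copies_per_molecule = 1` (the dynactin-like case) gives a modal count
of 1. The mean absolute step size recovers the configured ~26 AU per
fluorophore.

A shell interface wrapping the same functions ships as
`system.file("exec", "axontrack", package = "axontrack")`, with
subcommands `simulate-tracks`, `simulate-traces`, `detect-steps`,
`analyze-tracks`, `coloc`, `arrival-model`, `stats` and `full-pipeline`.

## Documentation

The methods vignette (`vignettes/transport-quantification.Rmd`) describes
the models, the analysis conventions and their parameters, what the
synthetic generators do and do not emulate, and the package's numerical
design choices.
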