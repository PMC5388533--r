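# flyfeedr

Quantitative analysis of short-term *Drosophila* feeding behavior, for
researchers running FLIC (Fly Liquid-Food Interaction Counter) recordings,
pharyngeal-pumping assays with dye-based volume readout, and calcium imaging
of pharyngeal taste neurons.

The package covers four pipelines, each exercisable end to end on synthetic
data with known ground truth:

- **FLIC event detection** — feeding contacts are segmented from raw sensor
  traces as maximal runs above a robust threshold over a running-median
  baseline: with baseline estimate *b(t)* and residual *r(t) = x(t) − b(t)*,
  samples with *r(t) > k·MAD(r)* (default *k* = 6) form candidate events,
  merged across gaps < 0.4 s and filtered at a 0.4 s minimum duration.
  Detections are validated against ground truth by greedy one-to-one
  interval matching (tolerance 0.5 s), yielding a detection rate and a
  false-positive rate.
- **Binned ΔF/F** — per 30-s bin after stimulus onset, the maximum of
  (F − F₀)/F₀, with F₀ the mean of the 10 usable frames immediately before
  onset and out-of-focus frames excluded, never interpolated.
- **Volume calibration** — a through-origin standard curve (slope in OD/μl)
  fitted to a two-fold dye dilution series converts background-subtracted
  OD630 extract readings into ingested volumes; ordinary least squares of
  volume on feeding time estimates the cohort ingestion rate (nl/s).
- **Pumping-assay bookkeeping** — the assay's inclusion rules (water
  pre-test > 10 s; non-responder after four refused presentations), total
  feeding time, swallowing rate, and pooled swallow-vs-time correlations.

## Worked example

Simulate one 15-minute FLIC well, detect its feeding contacts, and score
them against the simulator's ground truth:

```r
library(flyfeedr)

sim <- gen_flic_trace(flic_sim_config(seed = 1))
events <- detect_events(sim$trace)
summarize_contacts(events, window = c(0, 900))
#>      well_id n_contacts total_contact_time_s mean_contact_duration_s
#> 1 control_w1         23                 56.2                2.443478

validate_events(events, sim$truth, tol = 0.5)
#> FLIC validation: 23 true, 23 detected, 23 matched
#>   detection rate 100.0%, false-positive rate 0.0%
```

This well has 23 true contacts totalling ~56 s of contact time; the default
detector finds all of them with no false positives. Convert a fly's dye
reading into an ingested volume:

```r
curve <- fit_standard_curve(gen_dilution_standard(seed = 3))
curve
#> Standard curve: slope 0.1380 OD/ul (10 levels, RMS residual 0.001874)
od_to_volume(0.35, curve, background = 0.07)
#>   fly_id volume_ul below_background
#> 1   <NA>  2.029493            FALSE
```

A reading of 0.35 OD over a 0.07 background converts to ~2 μl ingested.

A command-line interface wrapping the same functions (subcommands
`simulate`, `flic-detect`, `flic-validate`, `dff`, `volume`,
`pump-summary`) is installed at
`system.file("cli", "flyfeedr.R", package = "flyfeedr")`.

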