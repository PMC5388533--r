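---
title: "Methods: quantifying Drosophila feeding across four assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Drosophila feeding across four assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyfeedr)
```

## Scope

`flyfeedr` quantifies short-term feeding behavior in *Drosophila* from four
kinds of raw records:

1. **FLIC traces** — capacitive sensor time series from a Fly Liquid-Food
   Interaction Counter, in which a fly touching the liquid food closes an
   electrical circuit and elevates the signal for the duration of the
   contact.
2. **ROI fluorescence time series** — per-frame mean intensities of a
   GCaMP-expressing neuron's cell body, used to compute binned maximum
   ΔF/F responses to a taste stimulus.
3. **Dye-extract absorbances** — OD630 readings of erioglaucine extracted
   from single flies, converted into ingested volumes via a standard curve.
4. **Pharyngeal-pumping session tables** — per-fly bout durations and
   swallow counts scored from video in an immobilized-fly assay, with the
   assay's inclusion rules applied before any aggregation.

A synthetic-data module generates all four input kinds with known ground
truth, which is how the detector and the calibration pipeline are
benchmarked below. Inferential statistics (ANOVAs, post tests) are out of
scope: the package produces the per-fly quantities those tests consume.

## FLIC event detection

The detector treats a feeding contact as a contiguous interval in which the
signal sits above the local baseline by more than a threshold:

1. **Baseline.** A running median over a `baseline_window_s = 120` s window
   (ends padded by reflection) tracks slow drift. The median is robust to
   the brief, sparse contact pulses riding on it: with ~2 contacts/min of
   median duration 2 s, events occupy under 10% of any window.
2. **Threshold.** Either an absolute height (a.u.) or, by default, 6 times
   the median absolute deviation of the baseline-subtracted residual
   (`threshold_mads = 6`). The MAD mode adapts to a trace's own noise
   level, which is what makes the thresholds "user-customizable" safely.
3. **Segmentation.** Maximal supra-threshold runs of samples become
   candidate events; runs separated by gaps shorter than
   `merge_gap_s = 0.4` s are merged; events shorter than
   `min_event_duration_s = 0.4` s are discarded. Event end times extend one
   sample period beyond the last supra-threshold sample, so a run's
   duration equals its sample count times the sampling period.

The merge gap deserves a note. Its purpose is to bridge momentary dropouts
*within* one contact. At the signal-to-noise regime the simulator emulates
(pulse amplitude 100 a.u., noise sd 5, threshold ≈ 6 MAD ≈ 9 noise sd), a
within-event sample essentially cannot fall below threshold, so the merge
rule only needs to span a single dropped sample — 0.4 s at 5 Hz. A longer
gap (e.g. 1 s) would routinely fuse *distinct* contacts separated by
sub-second pauses; under one-to-one matching against ground truth every
such fusion costs a miss, and more importantly it misstates the contact
count that the genotype comparison below relies on. Comparisons against the
merge and minimum-duration cutoffs carry a 1e-9 relative guard so that
float ties (a gap of exactly two sample periods) resolve identically
whatever the time origin; the detector is exactly time-shift equivariant.

**Validation** against ground truth uses greedy one-to-one matching in time
order: a detection matches a truth interval if the two overlap or their
boundary distance is at most `match_tolerance_s = 0.5` s; ties resolve
earliest-start first. The detection rate is matched/true; the
false-positive rate is unmatched detections over detections, defined as 0
when nothing was detected (avoiding 0/0 conservatively). When two true
contacts closer than the merge gap are fused into one detection, exactly
one of them can match — fusions are *not* forgiven.

### The synthetic benchmark

The accuracy benchmark generates 50 fifteen-minute traces at 5 Hz: baseline
0, square events of 100 a.u., Gaussian noise sd 5, a slow sinusoidal drift
of amplitude 10 a.u. (random period 200–400 s), ~2 events/min with
lognormal durations (median 2 s, shape 0.5). These are simulator choices —
the instrument's units and noise law are not standardized — set so that a
competent detector is neither trivially perfect nor hopeless; amplitudes
and rates are configurable. Overlapping simulated events are merged in the
ground truth, since a fly cannot be in two contacts at once. On this
benchmark the default detector recovers over 97.6% of true contacts with a
false-positive rate well under 1.8%, the accuracy reported for
ground-truth-scored FLIC analysis of this kind; `scripts/acceptance.R`
recomputes both numbers.

What passing this benchmark does **not** show: real FLIC noise is not
exactly Gaussian, real contacts are not square pulses, and leg touches may
produce lower-amplitude elevations than feeding licks (the package does not
attempt an amplitude-class distinction). The benchmark demonstrates
correctness of the segmentation logic and a realistic operating point, not
instrument-grade validation.

### Genotype contrast

For the freely-feeding comparison the simulator gives the mutant the same
contact *rate* as the control but three-fold longer bout durations (the
reported overconsumption phenotype). The pipeline
(simulate → detect → summarize over a 15-min window) is expected to return
a mutant:control total-contact-time ratio slightly *below* 3 and a contact
count ratio slightly below 1: contacts arriving as a Poisson process of
rate λ with mean duration L cover a fraction `1 − exp(−λL)` of the
recording, and distinct contacts that abut get merged in both ground truth
and detection. At 1 event/min (chosen for this comparison to keep overlap
low) the coverage calculation predicts a time ratio ≈ 2.8 and a count
ratio ≈ 0.9; the acceptance test bounds (time ratio in [2.5, 3.5], count
ratio in [0.8, 1.2]) come from that calculation, not from tuning.

## Binned ΔF/F

The calcium readout follows the standard fractional-change convention.
`compute_f0()` averages the 10 usable (non-excluded) frames immediately
before stimulus onset; if flagged frames fall in that window, the window
slides earlier until 10 usable frames are collected — this preserves the
"10 consecutive frames immediately before" intent under gaps rather than
silently averaging fewer frames. `bin_dff()` then reports, for each
complete 30-s bin *aligned to stimulus application* (bin 0 is 0–29 s after
onset), the maximum `(F − F0)/F0` over the bin's usable frames.

Handling of out-of-focus frames: they are dropped, never interpolated. A
bin that retains fewer than two thirds of its nominal frames is flagged
`low_coverage` (refocusing typically costs 5–10 s, less than a 30-s bin, so
losing more than 10 s is anomalous); a bin with no usable frames reports a
missing ΔF/F — never zero, which would understate a response.

The simulator's response kernel is
`g(u) = (1 − e^(−u/τr)) · e^(−u/τd)` normalized to unit maximum, whose peak
sits at `u* = τr·ln(1 + τd/τr)` after onset. The default kinetics
(τr = 13 s, τd = 120 s) place `u*` ≈ 30.2 s — a response that takes on the
order of 30 s to peak, landing in the 30–59 s bin, consistent with the slow
pharyngeal sugar responses this models. The default recording (onset 30 s,
then 300 s at 1 frame/s) yields exactly ten complete bins. ΔF/F is invariant
under positive rescaling of the whole trace, and the tests check binning
against a no-exclusion oracle: excising any ≤10 s window changes a bin's
ΔF/F by no more than the signal change across the excised frames.

The group dispersion in `response_timecourse()` is reported as both sd and
sem (the plotted error measure in this assay family is typically sem).

## Volume calibration

The dye standard is a 10-level serial two-fold dilution of the reference
erioglaucine solution read in at least triplicate. `fit_standard_curve()`
fits mean OD against level **through the origin** (slope `Σxy/Σx²` on the
level means): downstream conversion uses the slope alone, so a free
intercept would be dead weight; the RMS residual of the level means is
recorded so the choice can be audited. The level axis is expressed in
microliter-equivalents of the reference solution, which is what makes the
slope's unit OD/μl. Replicate readings at the lowest levels may dip below
zero after blank subtraction; only an all-zero standard is an error.

`od_to_volume()` subtracts the dye-free-fly background (mean over control
flies, `background_od()`) and divides by the slope. Readings below
background clamp to volume 0 with a `below_background` flag and a warning —
negative volumes are unphysical, and the flag preserves auditability.
The round trip `od_to_volume(slope·v + b, curve, b) = v` is exact on a
noiseless standard.

`fit_rate()` regresses per-fly volume (nl) on feeding time (s) by ordinary
least squares and reports the slope as the cohort ingestion rate with its
R². At the benchmark cohort size (n = 20) and the per-fly rate variability
implied by a pooled R² near 0.76 (rate CV ≈ 0.21), the OLS slope has an
analytic standard error close to 1 nl/s; the recovery tests therefore
assert agreement within three standard errors for a single cohort and
within 5% for the median over 200 cohorts. That spread is a property of the
assay's own scatter, not of the implementation.

## Pumping-assay bookkeeping

Two exclusion rules run before any aggregation, in this order: a fly that
drank water for **longer than 10 s** in the pre-test is discarded (exactly
10 s passes — the cutoff is a strict inequality, resolving the wording
"longer than 10 s" in the strict direction), and a fly that failed to
initiate feeding within its **first four presentations** is discarded as a
non-responder. Presentation outcomes are stored as a compact string
(`"NNIY"`); the 2 s offer / 3 s rest timing is metadata only. Under an
initiation probability *p* per presentation the non-responder fraction is
`(1 − p)⁴`, which the property tests check by simulation.

For included flies: total feeding time is the sum of bout durations, the
pumping rate is total swallows over total time (invariant under joint
scaling of bouts), and `pooled_correlation()` computes the squared Pearson
correlation over included flies only — excluded sessions carry missing
summaries and can never leak into an aggregate.

The cohort simulator's pump-rate parameters (mean 2.0 swallows/s, CV 0.13)
are calibration choices: the mean matches the observed concentration-
independent swallowing rate's order, and the CV is set so that the pooled
swallow-vs-time R² over a 140-fly cohort with feeding times U(5, 60) s has
expectation ≈ 0.92 under the variance decomposition
`R² = r̄²Var(t) / (r̄²Var(t) + E[t²]σr²)`. A *single* cohort's realized R²
scatters around that expectation with sd ≈ 0.013, so the acceptance test
evaluates the calibration in expectation over a fixed sweep of 25 seeded
cohorts rather than on one arbitrary draw; per-fly rates are drawn
lognormal (guaranteeing positivity) with the stated mean and CV.

## Numerical and degenerate-input choices

- Running median windows are rounded to an odd sample count; traces
  shorter than the window are a parameter error, not a silent fallback.
- `detect_events` on an empty trace returns an empty event table (not an
  error); a flat trace returns no events.
- Mean contact duration of zero contacts is reported as 0, not NaN.
- Validation with an empty truth set defines the detection rate as 1
  (nothing to find) and the false-positive rate as 0 when nothing was
  detected.
- All simulators restore the caller's RNG state; a fixed seed gives
  bit-identical outputs, and the CLI records the seed in every output
  header and run manifest.

## Problem sizes

The shipped tests and the acceptance script run the full FLIC benchmark
(50 × 15-min traces at 5 Hz), 200-cohort rate-recovery sweeps, and
25-cohort correlation sweeps; together they complete in a few seconds on a
single core, so the defaults are also the sizes we recommend for quick
reproduction.

## Known limitations

- The FLIC simulator's noise model (Gaussian + slow sinusoid) is a stated
  idealization; no distributional description of real instrument noise is
  available to emulate.
- No amplitude-based discrimination of contact classes (tasting touch vs
  ingestion) is attempted.
- The ΔF/F module assumes ROI extraction happened upstream; there is no
  image segmentation or motion correction.
- The standard curve is strictly linear; saturating (4PL-type)
  calibrations are out of scope.
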