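---
title: "Measuring anticipation and population synchronization in fly activity rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring anticipation and population synchronization in fly activity rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaseslope)
```

## The scientific problem

A circadian clock shows itself in behavior most convincingly through
*anticipation*: a gradual increase of locomotor activity that begins hours
before a predictable environmental transition (lights-off, or the warm-to-cold
step of a temperature cycle). An acute activity burst *at* the transition — the
startle response — needs no clock at all, so any quantification of clock
output must separate the ramp from the startle.

`phaseslope` implements a slope-based quantification of this anticipatory ramp
for populations of *Drosophila* recorded in Trikinetics DAM2 activity
monitors, under multi-phase entrainment protocols in which light–dark cycles
(LD), constant light or darkness (LL/DD), and 12 h:12 h 25 °C:16 °C
temperature cycles under constant light or darkness (LLTC/DDTC) follow each
other, optionally with a phase shift between regimes.

## From counts to the analysis substrate

1. **Binning.** Per-minute beam-crossing counts are summed into 30-min bins
   aligned to the analysis day's Zeitgeber time (ZT0 = lights-on under cyclic
   light, thermophase onset under cyclic temperature). Bin timestamps refer to
   the *bin start*: the value at ZT 690 min covers minutes 690–719. Bins with
   more than half of their minutes invalid (monitor errors, recording gaps)
   are treated as missing.
2. **Per-fly normalization.** Each fly's bins are divided by that fly's
   maximum bin and scaled to percent, removing inter-individual differences in
   overall activity. By default the maximum is taken over the fly's *entire
   binned recording*, so different analysis days of one experiment share a
   scale; a per-day window is available as an option
   (`daily_profile(..., normalize_window = "day")`). Flies with a zero
   maximum carry no signal and are excluded with a report.
3. **Population profile.** The per-bin *median* across flies is the population
   profile. The median rather than the mean is used deliberately: it reflects
   what the typical fly does, which is what "synchronization" means here.

## The slope statistics

On the median profile of an analysis day, two landmarks are located inside a
search window that ends at the Zeitgeber transition (default: the preceding
6 h):

* `zt_min` — the **last** bin attaining the window's minimum median,
* `zt_max` — the **first** bin after `zt_min` attaining the maximum median
  before the transition.

The tie rules are directional on purpose (latest minimum, earliest maximum):
they bracket the ramp as tightly as possible. The bin containing the
transition is excluded from the search so the startle response cannot be
mistaken for the anticipation peak; the exclusion width is configurable
(`exclude_bins`, default one bin — the minimal rule that removes the startle).
Landmarks are *population-level and shared across flies*; per-fly landmark
detection is deliberately not offered, because individual noisy minima/maxima
would turn the statistic into a selection bias measurement. Manual landmark
overrides are accepted and flagged in the output, since landmarks for noisy
genotypes are sometimes set by eye.

With activity `Act` in percent of each fly's maximum and time in minutes,

* the **theoretical slope** is the slope of the median profile between the
  landmarks: `Slo_the = (Act_max − Act_min) / (t_max − t_min)`;
* each fly's **individual slope** applies the same formula to that fly's own
  normalized activity at the same landmarks;
* the **experimental slope** `Slo_exp` is the median of the individual slopes.

For a worked example with published numbers: a median activity rising from 0
to 67.6 (% of max) over 180 min gives a slope of `67.6/180 = 0.38` (2
decimals) — `slope_between(0, 67.6, 511, 691)` reproduces this. (Landmark
times quoted to the minute, such as 511 and 691, are not multiples of the
30-min bin width; the exact minute bookkeeping behind such printed values is
not recoverable, so this package fixes the bin-start convention above and
treats differences of a minute as display rounding. The slope is unaffected:
both conventions give Δt = 180 min.)

The ratio `Slo_exp / Slo_the` is a **population synchronization index**. If
every fly behaves like the median, the two slopes agree and the ratio is 1
(an identity that holds *exactly* for identical flies, and is tested as
such). If individuals deviate from the median — misphased ramps,
unconsolidated activity — individual slopes collapse while the median profile
retains its shape, and the ratio falls below 1. A fly is classified
**anticipating** when its individual slope exceeds half the theoretical
slope; the percentage of anticipating flies is the second, more visual
synchronization readout.

On free-running days after temperature cycles (DD after DDTC), control
populations synchronize better while *decreasing* activity after the
subjective morning peak, so a mirrored **downhill** analysis is provided:
first bin attaining the maximum, last bin attaining the subsequent minimum,
negative slopes, and "anticipating" meaning *steeper* than half the
theoretical slope.

Statistics are computed at full precision in minutes; only display rounds ZT
to half-hours and slopes to two decimals. Group comparisons use the
Kruskal–Wallis rank test (χ² approximation by default; a seeded Monte-Carlo
permutation p-value is available for small groups — exact enumeration of all
label permutations is combinatorially out of reach even at 10 flies per
group, which is why the permutation option is Monte-Carlo) plus a seeded
percentile bootstrap (default 5000 resamples) of pairwise mean differences,
in the spirit of estimation statistics.

## What the synthetic generator emulates

`simulate_population()` draws per-minute Poisson counts from a piecewise-
linear rate function: a baseline with a multiplicative mid-day siesta trough,
crepuscular morning and evening ramps, and an exponentially decaying startle
impulse at every environmental transition. Ramps rise linearly from onset to
peak and decay linearly over a fixed fall window *after the peak* (rather
than being cut at the transition), which keeps the rate function well defined
in constant segments where no transition exists — the free-running decline
that the downhill analysis measures is exactly this fall. In constant
segments the phase advances at a configurable free-running period.

Defaults were chosen once, as study conditions, to mimic control recordings:
baseline 0.25 counts/min; evening ramp ZT 510 → 690 min (the ZT 8.5–11.5 h
landmark range typical of controls) with amplitude 2 counts/min; morning ramp
before (subjective) lights-on with amplitude 1; startle 3 counts/min with a
10-min half-life (large enough that the startle bin, not the anticipation
peak, is usually a fly's maximum bin — which is why control profiles peak
near 60–70% of max rather than 100, as real median profiles do); siesta depth
0.5 over ZT 270–510; free-running period 24 h.

Three labeled phenotype classes cover the biology the pipeline must
distinguish:

* **sync** — intact anticipation at the configured phase;
* **desync** — the evening ramp onset re-drawn uniformly over the cycle
  (stably misphased individuals);
* **flat** — no anticipation at all. Flat flies are *not* modeled as simply
  inactive: clock-disrupted genotypes show increased, unconsolidated activity
  (e.g. through the cryophase), so each flat fly receives a fly-specific
  tonic rate drawn uniformly from `tonic_range` (default 0.2–6 counts/min),
  constant across the day, with the startle retained and no siesta.

The tonic model matters for the synchronization index. Under per-fly max
normalization, an unconsolidated fly sits at a high, fly-specific level at
*every* bin: its individual slope is ≈ 0, yet across flies these levels
straddle the control values at both landmarks, so the per-bin medians — and
with them `Slo_the` — are barely moved. This is precisely the regime in which
`Slo_exp/Slo_the` drops toward one half while low-activity flat flies (whose
normalized values sit uniformly *below* the controls) would leave the ratio
near 1: with a 50/50 mixture, medians of values and medians of slopes both
land midway between the two clusters and the ratio cancels. The `cycDN_like`
preset (half the flies flat, the unconsolidated model above) reproduces the
clock-disrupted benchmark: synchronization ratio around 0.5–0.6 and roughly
half the flies classified anticipating.

What the generator does **not** emulate: sleep-bout structure, day-to-day
phase drift within a fly, masking differences between light and temperature,
or inter-fly correlation of any kind. Passing the simulation-based tests
therefore shows that the statistics behave correctly on populations with
known composition — not that any particular biological claim about real
recordings is true.

## Properties, and one deliberate limitation of the classifier

The test suite pins down, among others: exact ratio-1/100% identities for
identical flies; agreement of every statistic with plain-loop reference
implementations at `1e-12` on small populations; invariance of the entire
pipeline to a global rescaling of raw counts; monotone degradation of both
the ratio and the anticipating fraction as the desynchronized fraction grows;
and recovery of ground-truth anticipating fractions of 0.5 and 0.8 (n = 60)
to within ±10 percentage points.

At a ground-truth fraction of 0.2 the classifier does **not** recover the
truth, and cannot: when 80% of flies lack anticipation, the population median
loses its structure, `Slo_the` collapses toward landmark-selection noise, and
the half-threshold becomes so small that unstructured flies are flagged
"anticipating" roughly half the time. The estimate saturates near 45–50%
regardless of the true 20%. This false-positive floor is not an artifact of
the simulation — it is visible in published data, where fully clock-disrupted
genotypes still classify 50–60% "anticipating" against >80% for controls. The
half-threshold classifier separates synchronized from desynchronized
populations; it is not a calibrated estimator of the anticipating fraction
when anticipation is rare. The corresponding test documents this as an
expected failure rather than hiding it.

## Numerical and design choices

* **Validity masking.** DAM2 rows with status ≠ 1, and minutes missing from a
  file, are kept on the time grid as invalid rows with `NA` counts instead of
  being dropped — binning alignment stays trivial and nothing is silently
  imputed. How the original analyses handled monitor errors is not
  documented anywhere; this policy is this package's own.
* **One DAM2 dialect.** 42 tab-separated fields, date as `d mmm yy` with
  English month abbreviations (case-insensitive), strictly validated. A
  wrongly formatted file fails loudly with its row number.
* **Protocol day counting.** "TC day k" counts full ZT0→ZT0 days inside the
  temperature-cycle segment; the handover day created by the phase shift is
  excluded. The builder takes the number of LD and constant days as
  parameters rather than fixing them, since published protocols vary between
  two and three initial LD days.
* **Degenerate inputs.** A flat median profile in the search window, a
  minimum with no subsequent rise, or a non-positive theoretical slope are
  errors with actionable messages, not NaNs.
* **Problem sizes.** Simulation-based tests and the acceptance script use
  n = 60 flies (the typical per-genotype sample size of the experiments this
  emulates), 11-day protocols, and medians over 20 seeds; these sizes make
  the Monte-Carlo variability of the reported ratios small (≈ ±0.05 across
  seed sets) while each individual run stays below a second.

## Known limitations

Square-wave environments only (no twilight or temperature ramps); a single
42-field DAM2 dialect; population-level landmarks by design; the classifier
floor described above; and figure conventions (mean-based actograms,
median-based profiles, Tukey 1.5×IQR whiskers) fixed to match the field's
usual displays rather than configurable in every detail.
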