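---
title: "Methods: the neuronal transition probability cascade, its fitting, and the flip-flop analysis"
author: "ntpsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascade model, fitting, flip-flop analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ntpsleep)
```

## The model and its assumptions

`ntpsleep` treats the spectral power time courses of one NREM episode —
delta (1–4 Hz), sigma (12–15 Hz) and beta (18–25 Hz), in µV² on a
duration-normalised time axis — as the output of a three-mode firing-rate
cascade in a fixed-size generating population of brainstem neurons. The
assumptions, in decreasing order of load-bearing:

1. **Closed population.** The generating population has fixed size; mode
   occupancies always sum to it. This is enforced as a class invariant and a
   numerical property (conservation to 1e-9 in the closed form, exactly in
   the Monte Carlo counts).
2. **Memoryless instantaneous transitions.** Each neuron switches mode with
   a fixed probability per unit time, and a switch is instantaneous on the
   episode time scale. This yields the linear serial chain whose solution is
   the Bateman form used by `phaseOccupancy()`.
3. **Two steady dynamic states.** An episode alternates *towards* phases
   (cascade beta→sigma→delta, rates P_βσ, P_σδ) and *away* phases (reverse
   cascade, rates P_δσ, P_σβ). Within a phase the rates are constant; each
   phase starts from the end occupancy of the previous one, so trajectories
   are continuous at switchovers.
4. **External timing.** The cascade says nothing about *when* the phases
   switch; switchover times are free structural parameters, hypothesised to
   be set by a threshold flip-flop outside the cascade. The flip-flop module
   analyses that hypothesis generically: threshold crossings in one trace,
   state transitions in another, one-to-one temporal alignment.
5. **Linear readout.** Band power is mode occupancy times one per-band
   normalisation factor (constant across the episode), plus a constant
   background beta component of about 2 µV².

Time inside the core is always percent of episode duration (1 time unit =
1% of the episode); conversions to seconds or minutes happen only at I/O
boundaries.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| probability vector P | (0.13, 0.131, 0.2, 0.6) | per 1% of episode | the common set that fits all episodes; freeing it does not significantly improve fits (verified as a package test) |
| bin width | 2% (50 bins) | % of episode | the resolution at which band power is averaged and fitted |
| beta bias | 2 | µV² | constant background beta present throughout sleep, subtracted before fitting the beta scale; user-overridable per subject |
| smoothing | 3-point moving average | bins | pre-conditioning for peak/trough switchover detection only |
| detection prominence | 0.1 | fraction of series range | minimum swing for a peak/trough to count as a switchover (below: treated as residual noise) |
| band edges | 1–4, 12–15, 18–25 | Hz | delta/sigma/beta; the beta lower edge is subject-dependent in practice and therefore configurable |
| artefact filter | k = 4, 3-min window | — / s | flag a second when its RMS exceeds 4× the rolling-median background; the principle is fixed, these constants are this package's documented choice |
| epoch lengths | 4 s (spectral), 20 s (staging) | s | 4-s Hann FFT gives 0.25 Hz resolution; hypnograms are scored in 20-s epochs |
| REM combining rule | 15 min | min | REM bouts separated by less than 15 min of non-REM form one REM episode; a single REM epoch suffices to start one |
| alignment tolerance | half a bin (30 s at 60-s bins) | s | the intrinsic timing precision of binned threshold crossings |

Sleep onset is defined as the first stage-2 epoch, consistent with the
latency definition (lights-off to first stage 2).

## The fitting procedure

`fitEpisode()` is staged, reflecting that delta is measured much more
precisely than sigma or beta:

1. **Normalisation.** Delta is normalised to its maximum data value; the
   raw series is rebinned to 50 equal bins with missing bins carried as NA
   and excluded from every residual sum.
2. **Initial switchovers.** Peaks and troughs of the three-point-smoothed
   delta curve, alternating, starting with a *towards* phase at time 0. A
   leading trough (an initial decline before the first build-up) is
   dropped as noise. Peaks/troughs with a swing below the prominence
   threshold — including a terminal extremum with a negligible swing to the
   series boundary — are pruned; without the boundary rule, a noise wiggle
   in the last bins routinely produced a spurious final phase.
3. **Delta stage.** Switchover times are refined by coordinate search on
   the bin grid (moves of one bin while the delta R² improves, times kept
   strictly increasing and at least one bin apart), followed by a
   continuous one-dimensional polish within one bin per switchover. The
   delta scale is never searched: given the shape, the least-squares scale
   is analytic.
4. **Sigma/beta stage.** With the plan frozen, the sigma and beta scales
   are set to their analytic optima; the beta bias is subtracted from the
   beta data first.
5. **Goodness of fit.** Per-band R² = 100·(1 − SS_res/SS_tot); the overall
   R² is the Fisher-z combination of the three (below); classes are
   VG ≥ 60, G 40–60, F 19–40, and BF ("below fair") under 19 — the
   published scale stops at 19, so BF closes it. A runs test on residual
   signs is available as a diagnostic (`residualRunsTest`), reported and
   never enforced.

Freeing the probability vector wraps the staged fit in a Nelder-Mead search
on the log scale. On synthetic data this recovers the generating vector and
improves the overall R² only marginally — the package's restatement of the
finding that a single common vector suffices.

### Fisher-z aggregation: which transform

Averaging R² values directly is biased by the ceiling at 100%;
variance-stabilising first is standard. Two variants were candidates: apply
atanh to R² expressed as a fraction, or to its square root (the
correlation r). The package uses the square-root form,
z = atanh(√(R²/100)), for both `overallR2()` and `fisherZMean()`, because
only that form reproduces, from the reference cohort table at printed
precision, the published per-episode mean R² row — the fraction form misses
it by up to 0.3 — while both forms match the published caption combinations
at one decimal. For the same reason the cohort ANOVA and trend contrasts of
R² are computed on this z scale (the scale on which the published F
statistics recompute from the table); TA cycle counts are analysed raw.

### Degenerate and near-degenerate inputs

The middle-mode Bateman solution divides by P₂ − P₁, and the default
towards rates (0.13, 0.131) sit very close to that singularity. The
difference of exponentials is therefore computed as
−e^(−P₁T)·expm1(−(P₂−P₁)T), and below a relative rate difference of 1e-9
the exact equal-rate limit N₂ = (N₂(0) + N₁(0)P T)e^(−PT) is substituted.
`sigmaPeakTime()` returns the closed form ln(P₂/P₁)/(P₂−P₁) for a pure
first-mode start, NA when the middle mode is maximal at phase start
(inflow ≤ outflow at T = 0), and otherwise brackets the root of
inflow = outflow numerically. Monotone series yield single-phase plans, not
errors; zero-variance observed series make R² undefined and raise an error.

## Cohort statistics

The repeated-measures ANOVA is the textbook one-way within-subject
decomposition (F = MS_episode / MS_subject×episode), computed directly so
that it can run on the Fisher-z scale and report the pieces the polynomial
contrasts need; it is cross-checked against `stats::aov` in the tests. The
Huynh-Feldt epsilon comes from the within-subject covariance matrix and
adjusts only the p-value's degrees of freedom, never F. Polynomial trends
use the orthogonal contrasts (−3,−1,1,3), (1,−1,−1,1), (−1,3,−3,1); each is
tested against its own error term (per-subject contrast scores as a
one-sample problem, F(1, n−1)), and its share of the episode effect is its
SS over the episode SS — the three shares sum to 100 exactly by
orthogonality.

## The flip-flop alignment analysis

`detectCrossings()` emits an event at every sign change of
(trace − threshold) with linear interpolation between bin centres; events
alternate in direction structurally. `detectStateTransitions()` applies
the same smoothed peak/trough machinery as switchover detection to an SWA
trace, then re-centres each extremum on the unsmoothed trace within one
bin: smoothing an asymmetric rise/decay (fast rise, slow saturating decay
or vice versa) drags its extremum systematically one bin off, which a
half-bin matching tolerance cannot absorb. `alignEvents()` matches
crossings to reference transitions greedily by ascending absolute time
difference under a one-to-one constraint — the minimal formalisation of
matching events by visual alignment; no tie-breaking beyond "smallest
offset first" is defined, and this is a package choice. Thresholds are
user-supplied; `estimateThreshold()` (midpoint of the 10th/90th percentile
envelopes) is an explicitly labelled heuristic.

The binning effect is demonstrable, not just asserted: a sharp sub-bin peak
straddling a bin boundary is split between the neighbouring bins at about
half its amplitude, so a crossing present in the unbinned signal can vanish
after coarse binning. The test suite constructs exactly this case.

## What the synthetic generators emulate — and what they do not

- `generateEpisodeData()` inverts the fitting problem: simulate, scale,
  multiply by lognormal noise (unit median; power is positive with roughly
  scale-proportional spread), drop bins at random. Real artefacts cluster
  in time; the generator's missingness is independent per bin.
- `generateCohort()` draws per-episode TA counts as 1 + Binomial(8, p) with
  p set so the means rise as (5.2, 6.7, 6.8, 7.1) across the night. A
  shifted Poisson was considered and rejected: its dispersion is more than
  double the between-subject spread actually observed in reference cohort
  data of this kind, and with it a 30-subject cohort cannot reliably expose
  the rising trend the generator builds in. Switchover times are drawn by
  stick-breaking (Dirichlet phase lengths) with a minimum phase length of
  min(8, 40/TA)% — a fixed 4-bin minimum is impossible for TA ≥ 7, which
  real episodes reach.
- `generateScnSwa()` produces a two-level SCN-like trace (levels 100 ± 50%
  of mean, slow sinusoidal baseline, Gaussian noise) switching at a known
  schedule, and an anti-correlated SWA trace relaxing toward high/low
  targets with rate 0.003/s (time constant ≈ 5.5 min) so the build-up and
  decline span a typical phase rather than saturating early — a saturated
  response has noise-determined extrema and no usable phase markers. With
  noise SD at or below 10% of the switching amplitude, crossing/transition
  alignment at one-bin tolerance recovers at least 90% of events (a
  packaged test); above that bound the rate degrades smoothly.
- `generateSyntheticEeg()` sums three Butterworth band-limited noise
  carriers whose envelopes follow the square roots of the model's band
  powers. It reproduces band-power time courses, not EEG morphology: no
  spindles, K-complexes, slow-oscillation waveform shape, or
  non-stationarity within bins. Passing pipeline tests therefore show the
  spectral chain and fitter are correct, not that real EEG will fit this
  well.

All generators are pure functions of their parameters and seed.

## Problem sizes in the shipped tests

The suite fits 50-bin episodes; the noisy-recovery study uses 100 seeded
replicates at 10% multiplicative noise (two-switchover plans), the Monte
Carlo convergence checks use 10⁴ neurons for the single-run bound and
200 × 200-neuron replicates for the mean, and the synthetic full night is
four 16-minute episodes at 128 Hz. These sizes give stable statistics for
every property tested while keeping a full run of the suite around half a
minute.

## Known limitations

- Switchover refinement is a local search seeded by peak/trough detection;
  a grossly wrong initial plan (e.g. prominence set far too high) is
  refined, not replaced. There is no global stochastic optimisation by
  design.
- The quality classes and the probability vector are taken as given for
  human overnight sleep in young adults; nothing in the package adapts them
  to other species, ages or pathologies.
- The artefact filter's constants (k = 4, 3-min rolling median) implement
  the stated principle but are this package's choice; tune them per
  laboratory.
- `alignEvents()` rates depend on the tolerance; at the default half-bin
  (or one bin when both series carry binning error) the rate is meaningful,
  at large tolerances it saturates trivially.
- Episode segmentation assumes Rechtschaffen–Kales 20-s staging; no
  automatic staging is provided or planned.
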