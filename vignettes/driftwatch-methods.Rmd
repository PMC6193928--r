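---
title: "Methods: from PIT detections to the diel egg-predator mismatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from PIT detections to the diel egg-predator mismatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`driftwatch` infers two hourly time series that are never observed
directly — the availability of drifting asp eggs and the presence of their
egg predator, bleak — from passive-telemetry detection logs, and asks
whether their 24-hour distributions overlap. This vignette is the
package's own account of the models involved, the assumptions they make,
the parameters that matter, and the choices taken where the design was
genuinely open.

## From detections to presence

A PIT reader cycles at up to 10 energize/receive cycles per second, so a
fish holding inside an antenna field produces a read every tenth of a
second. `dedupe_detections()` collapses runs closer than `min_spacing_s`
(default 1 s, per individual, antennas pooled) to tame volume; because
this spacing is four orders of magnitude below the bout gap threshold it
cannot move a bout boundary.

`segment_bouts()` applies the gap rule: consecutive detections of one
individual belong to the same presence bout when separated by at most
`gap_hours` (default 2 h); a longer silence means the last detection was
the departure. Two conventions had to be fixed:

* **Inclusive boundary.** A gap of exactly two hours merges. "Within a
  two-hour period" reads as inclusive, and determinism requires picking a
  side.
* **Single-detection bouts** get duration zero but are retained — there
  is no minimum-duration rule in the field protocol, and discarding them
  would silently drop animals. For presence fractions and egg allocation
  they count as full membership of their containing hourly bin.

All time between the first and last detection of a bout counts as
presence, including time the fish may have spent between the three
antennas; the antennas are pooled as a presence proxy and antenna identity
is kept only as metadata.

Eligibility mirrors the field campaign's processing: long-lived asp are
analysed only from one year after tagging (same-season behaviour may be
disturbed by capture and surgery), short-lived bleak from one day after
tagging; male asp are excluded throughout, since egg availability is a
female quantity and males are never limiting.

## Egg availability

The eggs a female carries scale with her mass at spawning, but her length
was measured at tagging, at least a year earlier. The chain is:

1. **Individual growth projection.** A population von Bertalanffy curve
   \(L(t) = L_\infty(1 - e^{-K(t - t_0)})\) is fitted to scale-read
   age–length pairs (`fit_growth()`, Levenberg–Marquardt, fixed
   initializer \(L_\infty^{(0)} = 1.05\max L\), \(K^{(0)} = 0.2\),
   \(t_0^{(0)} = 0\) for reproducibility). Each female is then
   *individualized by rescaling \(L_\infty\)* so her curve passes exactly
   through her observed tagging length at her scale age:
   \(L_{\infty,i} = TL_{tag} / (1 - e^{-K(a_{tag}-t_0)})\). A
   multiplicative anchor keeps projected lengths positive and bounded,
   which an additive offset would not; this is a design choice, made here
   because the individualization scheme is otherwise underdetermined.
   A recapture length measured in the spawning year replaces the
   projection outright — the true increment is better than any model.
2. **Length to weight.** \(W = a\,TL^b\) with \(a = 0.00744\),
   \(b = 3.046\), *TL in centimetres and W in grams*. The unit pairing is
   forced: with these coefficients, millimetre input would produce
   tonne-scale fish.
3. **Weight to eggs.** \(E = GSI \cdot W / m_{egg}\). The defaults
   (GSI = 0.15, egg mass 3.5 mg) are literature-scale cyprinid
   placeholders exposed as configuration, not measured constants. Every
   *proportion* the pipeline reports — diel shares, z-scored model
   coefficients, R² — is invariant to rescaling either parameter (an
   acceptance test verifies this to 1e-9), so their absolute values only
   matter if absolute egg numbers do.

`allocate_eggs()` spreads each female's eggs at a single uniform rate
over the union of her season bouts (rate = fecundity / total presence
time). A single rate across visits, rather than per-visit
renormalization, is the natural reading of "time spent on the spawning
ground" — and with one rate the two are equivalent anyway. Conservation
is exact: binned eggs sum to total fecundity to floating-point error.

The central assumption — that presence time is a proxy for spawning
activity — is inherited from the field design and cannot be validated
inside the package; females could in principle gather at night and spawn
at departure. The synthetic generator makes the same assumption, so
passing recovery tests demonstrates the inference chain is faithful to
the model, not that the model is faithful to fish.

## Day, night, and the solar boundary

"Night" needs a boundary. `solar_times()` implements the NOAA
solar-position algorithm in its Julian-century form (mean solar longitude
and anomaly, equation of centre, apparent longitude, corrected obliquity
→ equation of time and declination → hour angle at zenith 90.833°), with
one refinement pass that re-evaluates the solar angles at the provisional
event time — near the equinoxes declination moves ~0.4°/day, enough to
shift sunrise by minutes at 50° latitude. The tests hold it within two
minutes of an independently coded one-pass NOAA spreadsheet
implementation across ±60° latitude; typical agreement is below one
minute.

Which twilight the original day/night split used is unknown; the default
is geometric sunrise/sunset (zenith 90.833°), with civil twilight
(zenith 96°) available via `twilight = "civil"`. Hourly bins get
*fractional* day/night weights (a bin straddling sunrise is split
proportionally); the binary covariate for the models is the majority
label, with ties (an exact half-bin) labelled day. Share summaries use
the fractional weights to avoid boundary bias. Site coordinates default
to 49.578497° N, 15.251671° E and are configurable.

## The two mixed models

The hourly design table joins binned eggs, summed fractional bleak
presence, day-of-year, the period label (night = 1), and temperature
(nearest logger sample; bins with no sample within 90 minutes are dropped
and counted). All model columns are z-scored (`centre_scale()`),
including the binary period covariate and, by default, the responses —
"centred and scaled" is read as applying to the data, with
`scale_response = FALSE` exposed for the narrower reading. Scaling
metadata is retained so effects can be expressed on original scales.

* **Egg model:** eggs ~ period + date + bleak + temperature, random
  intercept for year. Year is the random effect named by the analysis
  plan; the bleak-identity alternative that appears in one results table
  is available through `egg_random` but is not the default, since the
  methods text is the more deliberate statement.
* **Bleak model:** per-individual presence fraction ~ period + date +
  eggs (+ temperature entering the full model, available to be
  eliminated), random intercept and slope by bleak identity. The random
  slope is on date — the only continuous within-individual covariate
  spanning the season; the original specification does not name it.
  The response is a linear (Gaussian) model on the presence fraction,
  not a logistic one, mirroring the use of LMM t-statistics for presence
  in this literature; with `scale_response` the Gaussian choice also
  keeps the scale-invariance property exact.

Fits are REML through `lmerTest` (Satterthwaite denominator degrees of
freedom per fixed effect). Nakagawa–Schielzeth R² is computed in the
package: \(\sigma^2_f\) is the variance of the fixed-effect predictor,
\(\sigma^2_r\) the mean diagonal of the marginal random-effect covariance
\(Z\Sigma Z^\top\) (Johnson's random-slope extension), \(\sigma^2_e\) the
residual variance; marginal R² = \(\sigma^2_f/\) total, conditional adds
\(\sigma^2_r\) to the numerator. Backward elimination (`stepwise_aic()`)
refits by maximum likelihood with each fixed term dropped, removes the
best drop while AIC improves, holds the random structure fixed, and logs
every candidate. Singular fits are flagged, never silently accepted;
grouping factors with fewer than two levels make the fit degenerate
gracefully to OLS (zero random variance, residual degrees of freedom),
which the single-season case exercises.

`kendall_tau()` is an O(n²) concordant/discordant count with tau-b tie
correction. For n ≤ 30 the p-value comes from a seeded Monte Carlo
permutation distribution (10,000 draws; exhaustive enumeration of n!
orderings is infeasible, so "exact" is approximated to Monte Carlo
accuracy), above that from the normal approximation with tie-corrected
variance of S.

## The synthetic generator

`generate_season()` emits the three canonical inputs plus ground truth.
Its defaults *are* the study conditions: a 14-day early-April season,
230 asp females (the larger year; 98 in the smaller) making 1–3 visits,
23 bleak (35 in the other year), visit nocturnality probability 0.63,
mean visit duration 6 h, three antennas at 10 Hz, hourly temperature with
a rising trend (7 °C start, +0.15 °C/day) and a small afternoon-peaked
diel cycle (±0.8 °C). Female lengths are drawn at 49.5 ± 8.0 cm, males at
47.0 ± 5.3 cm, bleak at 11.9 ± 1.0 cm; scale ages are consistent with the
configured growth truth curve (defaults \(L_\infty = 85\) cm,
\(K = 0.18\)/yr, \(t_0 = -0.5\) yr; ages are obtained by inverting the
curve at the drawn length plus scale-reading noise, giving spawners
mostly 3–7 years old).

Design choices that required judgement:

* **Visit placement.** A visit is nocturnal with probability
  `night_spawn_prob`; its centre is drawn from a truncated normal around
  the middle of that night's (or day's) window — a circular-mixture shape
  centred on midnight/midday — and the whole visit is constrained to lie
  inside its window. The containment makes the realized nocturnal egg
  fraction converge to `night_spawn_prob`, which is the generator's
  contract; an unconstrained mixture leaks across twilight and biases
  the truth downward.
* **Visit durations** are lognormal with mean 6 h and CV ≈ 1/3 rather
  than exponential. An exponential's heavy tail is asymmetrically
  truncated by the shorter night window (~11 h night vs ~13 h day in
  early April), which would again bias the truth fraction below the
  configured probability; the concentrated distribution keeps night and
  day visits distributionally identical. It is also the more realistic
  shape for visits described as averaging six hours.
* **Bleak behaviour**: present on a given day with probability
  `bleak_day_presence` (default 0.75, rising slightly across the season),
  arriving up to 30 min before sunrise and leaving up to 45 min before
  sunset; with probability `bleak_night_stay_prob` (default 0.08) an
  individual stays the night. Overnight stays, not brief nocturnal
  returns, are what produce the observed pattern of a small mean night
  share with large between-individual spread.
* **Detections** are antenna passes (Poisson, default 6/h while present,
  forced at interval endpoints so reconstructed bout boundaries can match
  truth exactly) emitting short read bursts snapped to the reader's
  0.1 s cycle grid; a read colliding with an earlier one on the same
  antenna and cycle is served on the next free cycle, so no antenna ever
  exceeds 10 Hz.
* **Planted effects and what is testable.** The generator plants
  unambiguous partial effects for period (night raises eggs, lowers
  bleak presence) and date (visit intensity decays for eggs, bleak
  presence rises); the sign tests assert exactly these. Temperature is
  deliberately not asserted: it is constructed collinear with date
  (seasonal trend) and period (diel cycle), so its partial sign is not an
  independently plantable quantity.

What the generator does *not* emulate: river hydraulics and egg drift,
movement between antennas, tag loss or mortality, detection-probability
decay, non-stationary weather. Tests passing on synthetic seasons show
the *inference chain* recovers what the generative model planted — they
are silent on whether real fish follow that model.

## Numerical conventions and problem sizes

* All internal time is UTC (POSIXct); local-time inputs convert at the
  boundary. The canonical CSV dialect round-trips byte-for-byte.
* Egg conservation is asserted at 1e-9 relative; allocation is checked
  against an exact one-second-lattice oracle.
* The growth fit is deterministic given its fixed initializer; order of
  input pairs affects results only at numerical-roundoff level (~1e-7
  relative). At the validation conditions (n = 300, 2% multiplicative
  length noise, ages 2–12), \(L_\infty\) and \(K\) are recovered within
  5% relative; \(t_0\), which extrapolates the curve to zero length, has
  sampling error an order of magnitude larger, and the corresponding
  test documents that a 5% relative band does not hold for it.
* Test and validation problem sizes: bout segmentation is checked against
  an independent pairwise-chaining oracle on 200 random instances up to
  10⁴ detections; diel recovery on 20 generated seasons at full study
  size; mixed-model recovery on simulated data at n = 2000 (estimates,
  R²) and 50 replicates at n = 400 (stepwise null elimination); Kendall
  tau against brute force on 100 random vectors up to n = 50.

## Known limitations

* Presence-as-spawning is assumed, not tested (see above).
* The GSI and egg-mass defaults are placeholders; absolute egg counts
  should not be interpreted, only their distribution in time.
* The Gaussian presence model can predict outside [0, 1]; it is used for
  comparability of t-statistics, not for prediction.
* Single-season datasets lose the year random effect (OLS fallback), so
  conditional R² for the egg model is only meaningful with two or more
  seasons.
* The day/night boundary is sharp; crepuscular behaviour is represented
  only through fractional bin weights, not modelled.
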