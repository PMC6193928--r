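# driftwatch

Tools for quantifying the diel mismatch between drifting fish eggs and
their egg-eating predators from passive PIT telemetry.

## The problem

Asp (*Leuciscus aspius*), a large rheophilic cyprinid, releases drifting
eggs on gravel spawning grounds in early spring; bleak (*Alburnus
alburnus*), a small visually foraging cyprinid, eats those eggs — but only
while it can see them. Whether spawners concentrate egg release in the
hours when the predator is absent (the predator-avoidance hypothesis) is a
question about the *24-hour timing* of two quantities that are never
observed directly: the availability of drifting eggs and the presence of
the predator. Both must be inferred from antenna detection logs of tagged
individuals.

`driftwatch` implements that inference chain end to end:

1. **Ingest** — read detection logs (timestamp, antenna, 12-digit tag
   code), a tagging registry, and an hourly temperature series; collapse
   sub-second re-detections from readers cycling at 10 Hz.
2. **Presence bouts** — segment each individual's detections with a
   two-hour gap rule (a longer silence means the last detection was the
   departure), then apply eligibility filters: asp analysed from one year
   after tagging, bleak from one day, male asp excluded.
3. **Egg availability** — project each female's length to the spawning
   year with an individual-based von Bertalanffy curve anchored through
   her scale-read age and tagging length (recapture lengths override the
   projection), convert length to weight by the allometric law
   W = a·TLᵇ (a = 0.00744, b = 3.046; TL in cm, W in g), estimate
   fecundity from a gonadosomatic index, and spread each female's eggs
   uniformly over the time she spent on the spawning ground.
4. **Diel labelling** — sunrise/sunset from the NOAA solar-position
   algorithm (zenith 90.833°; civil twilight optional), fractional
   day/night weights per hourly bin.
5. **Statistics** — two linear mixed models (lme4/lmerTest backend) with
   Satterthwaite degrees of freedom, Nakagawa–Schielzeth marginal and
   conditional R², backward AIC selection, and Kendall rank correlation:
   one model for binned egg numbers (covariates: period of day, day of
   year, bleak presence, temperature; random intercept for year) and one
   for per-individual bleak presence (period, day of year, eggs;
   random intercept and slope by bleak identity).
6. **Synthetic seasons** — a generator that emits registry, detection log
   and temperature series with known ground truth for every downstream
   quantity (night-spawning probability, per-female fecundity, true
   presence intervals), used to validate the whole chain.

## Worked example

Generate a two-season synthetic study at realistic animal counts and run
the full pipeline:

```r
library(driftwatch)

study <- generate_study(list(
  synth_config(seed = 101, season_start = "2016-04-01",
               season_end = "2016-04-15", n_asp_females = 98, n_bleak = 35),
  synth_config(seed = 102, season_start = "2017-04-01",
               season_end = "2017-04-15", n_asp_females = 230, n_bleak = 23)))

cfg <- run_config(study$detections, study$registry, study$temperature,
                  seasons = list(c("2016-04-01", "2016-04-15"),
                                 c("2017-04-01", "2017-04-15")),
                  seed = 5)
res <- run_pipeline(cfg)

res$summary$egg_night_share_pct    # 63.4591
res$summary$bleak_day_share_pct    # 92.252
print(res$model_eggs$model)
```

```
Linear mixed model: eggs ~ period + date + bleak + (1 | year)
        term   estimate      se       df          t         p
 (Intercept) -2.933e-14 0.41610   0.9956 -7.049e-14 1.000e+00
      period  6.821e-01 0.07643 668.0000  8.924e+00 4.288e-18
        date -2.716e-01 0.03263 667.0000 -8.323e+00 4.839e-16
       bleak  3.605e-01 0.07958 667.8000  4.530e+00 6.999e-06
Marginal r2 = 0.177; conditional r2 = 0.459; AIC = 1661.4
```

Reading: the night bins hold substantially more eggs (positive `period`
coefficient, night coded 1, all covariates z-scored), egg numbers decline
through the season (negative `date`), and backward AIC selection dropped
temperature from this run's model. The per-day/per-individual summaries
put ~63% of eggs at night while bleak are present ~92% of the time during
daylight — the generator's planted diel mismatch, recovered by the
pipeline. `res$summary` also carries the bleak-presence model, both
R² pairs, and the Kendall correlation between daily egg and bleak totals;
with `out_dir` set, `run_pipeline()` writes the CSV/JSON bundle
(`bouts.csv`, `biomass.csv`, `eggs_bins.csv`, `diel_profile.csv`, model
tables, `summary.json`, `manifest.json`).

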