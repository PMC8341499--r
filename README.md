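# turbavoid

Wind farms can displace soaring raptors from the landscape around turbines
(avoidance, i.e. functional habitat loss) or kill them through collision
with moving blades; which process dominates, and what modulates it, decides
how a wind farm's impact should be assessed. `turbavoid` is an R package
for quantifying **meso-avoidance of wind turbines by GPS-tagged birds**
from telemetry, per-turbine commissioning dates, 3-hourly SCADA
(wind-speed / rotor-speed) records and a 50-m habitat-preference raster
("GET" scores 1–10, higher = more preferred). It is written for movement
ecologists and wind-farm impact analysts.

The core analysis:

* **Telemetry QC** — fixes kept only with HDOP < 3.5, plausible altitude
  (≤ 6 km asl), and between sunrise and sunset computed per fix at its own
  location and date (sun centre at −0.833°).
* **Approach geometry** — for a fix, the planar distance to the nearest
  turbine hub; for a flight line (consecutive fixes ≤ 5 min apart), the
  closest 2-D approach `d2d` at fraction *t* along the segment. Altitude is
  interpolated to the pass point and the 3-D distance follows by
  trigonometry:

  `d3d = sqrt(d2d² + (alt(t) − hub_alt)²)`,  `hub_alt = base_elevation + hub_height`.

* **Datasets** — records within a 1-km buffer of their nearest turbine,
  labelled BEFORE/AFTER the turbine's operation date, joined to the
  simultaneous (3-h-rounded) SCADA wind speed and blade-motion status, with
  GET scores at the turbine (5-pixel rook-neighbourhood mode) and at the
  record location.
* **Models** — Gaussian linear mixed models of `d3d` fitted by maximum
  likelihood with crossed random intercepts for wind-farm, turbine and bird
  identity: an enumerated 12-model candidate set (turbine GET × phase ×
  tag GET) for before/after data and a 27-model set (wind × turbine GET ×
  blade status × flight-line GET) for after-operation data, selected by
  AIC/BIC (BIC wins on disagreement), with Nakagawa marginal/conditional
  R², per-factor shares of explained variance, and partial-effect grids.
* **Synthetic data** — a fully seeded generator (autocorrelated GET
  landscape, two wind-farm layouts of 33 and 66 turbines, AR(1)-Weibull
  wind with cut-in-driven blade stoppage, biased correlated-random-walk
  telemetry with injected turbine avoidance) so the whole pipeline is
  testable end to end without any field data.

## Worked example

```r
library(turbavoid)
library(dplyr)

study <- simulate_study(sim_config(seed = 2026, steps_before = 300,
                                   steps_after = 300, n_birds_gsm = 4,
                                   n_birds_argos = 2))
fixes <- qc_filter(study$fixes)
qc_report(fixes)
#> $input
#> [1] 3600
#> $retained
#> [1] 3038
#> $excluded
#>             hdop missing_altitude  altitude_gt_max            night
#>              410               32                3              117

records <- build_before_after_records(fixes, study$turbines, study$raster)
summarize_distances(records, phase)
#> # A tibble: 2 × 6
#>   phase   mean    sd  lo95  hi95     n
#>   <chr>  <dbl> <dbl> <dbl> <dbl> <int>
#> 1 AFTER   552.  289.  97.7  977.   818
#> 2 BEFORE  381.  270.  80.6  955.  1037

fit <- fit_lmm("postop", records)
tidy(fit)
#> # A tibble: 2 × 7
#>   term        estimate    se ci_lo ci_hi     df        p
#> 1 (Intercept)     287.  19.4  249.  325.   60.7 7.99e-22
#> 2 postopAFTER     132.  11.2  110.  154. 1807.  6.21e-31

r2_nakagawa(fit)
#> # A tibble: 1 × 2
#>   marginal conditional
#> 1   0.0506       0.378
```

Reading the output: after turbines begin operating, the mean 3-D distance
of this simulated population to its nearest turbine hub rises from 381 m
to 552 m; the mixed model attributes a +132 m displacement to the
operational phase (95% CI 110–154 m) after absorbing farm, turbine and
bird identity, and fixed + random effects together explain 37.8% of the
distance variance (5.1% from the fixed effect alone). The QC report shows
every excluded fix attributed to exactly one rule.

`autoplot(fit)`, `plot_distance_by_get()` and `effect_grid()` produce the
usual partial-effect displays; `run_pipeline()` (or
`inst/scripts/run_pipeline.R` from a shell) chains simulate → QC →
datasets → fits → summaries with a JSON manifest of every threshold.

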