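---
title: "Quantifying turbine avoidance from raptor telemetry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying turbine avoidance from raptor telemetry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turbavoid)
library(dplyr)
```

## The scientific problem

A wind farm can harm soaring birds two opposite ways: by displacing them
from the airspace around turbines (avoidance — effectively habitat loss)
or, if they are *not* displaced, by collision with moving rotor blades.
`turbavoid` implements a before–after, telemetry-based test of avoidance
at the scale of individual turbines, and an after-operation analysis of
how proximity depends on wind speed, blade-motion status and the intrinsic
habitat preference of the ground under bird and turbine.

The response throughout is the **3-D distance from a telemetry record to
its nearest turbine hub**. Working in three dimensions matters: a bird
crossing high above an array is not "at" the turbines, and 2-D distances
would overstate its exposure.

## From raw fixes to modelling datasets

**Quality control.** A GPS fix enters the analysis only if its horizontal
dilution of precision is strictly below 3.5 (commensurate with the 50-m
habitat raster), its altitude is present and at most 6 km asl, and it
falls between sunrise and sunset computed for the fix's own latitude,
longitude and date with the sun's centre at −0.833° (geometric rise/set
with standard refraction; birds are assumed to roost at night, so
night-time fixes carry no information about turbine response). Rules are
applied in a fixed order — HDOP, altitude missing, altitude range,
night — so each rejected record has exactly one recorded reason and QC
reports always conserve counts. Fixes exactly at the sunrise or sunset
instant are retained (closed interval); the boundary choice is arbitrary
but must be deterministic. Solar events use the standard NOAA
solar-position equations with one refinement iteration at the estimated
event time, which agrees with a Meeus-style ephemeris to well under a
minute; polar day/night are flagged explicitly rather than returned as
fictitious times.

**Flight lines.** High-cadence (GSM-tag) fixes are joined into straight
flight segments; consecutive fixes more than 5 minutes apart are not
joined, because the straight-line approximation degrades with gap length.
The closest approach of a segment to a hub is found in the horizontal
plane first; the bird's altitude is interpolated linearly to that pass
point; the 3-D distance follows by trigonometry. This *2-D-first*
convention is deliberate: it is not the true 3-D minimum over the segment,
and because a straight segment cannot represent last-moment evasive
manoeuvres the resulting distances are conservatively low. Zero-length
segments legally reduce to point distance, so stationary birds do not
break the geometry.

**Altitude datum.** Tag altitudes are metres above sea level and hub
heights metres above ground; both are placed on the asl datum via the
turbine's base elevation before differencing. This is the only internally
consistent reading when the terrain under bird and turbine differ, and it
is the package default.

**Buffer and pairing.** Only records whose nearest turbine (2-D planar
distance for fixes, 2-D closest approach for segments) lies within 1 km
enter the datasets — beyond that, turbines cannot plausibly influence
flight, and including such records would dilute any displacement signal.
Each record pairs with its single nearest turbine, matching the
turbine-identity random effect in the models; choosing the nearest in 2-D
(rather than 3-D) keeps the pairing consistent with the buffer rule.

**Operational phase and SCADA.** A record earlier than its paired
turbine's operation date is BEFORE (construction time folds into BEFORE,
which biases the before/after contrast toward zero — a conservative
choice); the operation instant itself is AFTER. For after-operation
records the closest-pass time is rounded to the nearest 3-hour grid
instant (an exact 90-minute tie rounds up) and the simultaneous wind
speed and blade-motion status joined by exact key; records without a
SCADA match are dropped and counted. Rotor speed binarises to
STILL/MOVING at exactly 0 rpm by default (configurable) since no
manufacturer threshold is assumed.

**Habitat preference.** The GET surface scores every 50-m pixel 1–10 for
intrinsic eagle habitat preference (≥ 6 increasingly preferred); the
package consumes it as a raster and does not re-derive it. A turbine's
score is the mode of its own pixel and the four edge-adjacent (rook)
neighbours — "four surrounding pixels" forces rook rather than queen
adjacency — with modal ties broken to the *highest* tied score, a
precautionary choice toward calling turbine sites preferred. A record's
score is the single pixel under the fix or under the closest-pass point
(not averaged along the flight line). Pixels are half-open (west and
north edges inclusive) so any point has exactly one owner.

## The mixed models

Both analyses model `d3d` with Gaussian linear mixed models fitted by
**maximum likelihood** (not REML), so that AIC and BIC are comparable
across fixed-effect structures, with independent crossed random
intercepts for wind-farm, turbine and bird identity — repeated records
from the same farm, turbine and bird are not independent, and these three
factors absorb that structure. GET scores enter as numeric covariates
(single slope per score), not factors.

The before/after candidate set enumerates 12 models over turbine GET,
operational phase and tag-location GET: the null (random effects only),
the three singles, the three pairs each with and without their two-way
interaction where both mains are present, the additive triple and the
saturated triple (all two-ways plus the three-way). Interactions are only
fitted among main effects included in the model. The after-operation set
enumerates 27 models over wind speed, turbine GET, blade status and
flight-line GET up to the saturated four-way model.

**Selection** takes the model minimising both AIC and BIC when they
agree; on disagreement the BIC-best model wins by default (BIC's stronger
complexity penalty favours an interpretable model; a flag flips the rule
to AIC), and residual ties break to fewer degrees of freedom. Estimation
delegates to `lme4::lmer` with the deterministic `bobyqa` optimiser at
fixed settings; `lmerTest` supplies Satterthwaite degrees of freedom and
p-values, and confidence intervals are Wald. Singular fits (variance
components at the zero boundary) are returned flagged, never silently
dropped; in small fixtures a random factor observed at a single level is
removed with a warning rather than fitted at the boundary.

**Variance decomposition.** With `sigma_f2` the variance of the
fixed-effects linear predictor over the data, `tau_g` the
random-intercept variances and `sigma2` the residual variance,

* marginal R² = `sigma_f2 / (sigma_f2 + sum(tau) + sigma2)`,
* conditional R² = `(sigma_f2 + sum(tau)) / (sigma_f2 + sum(tau) + sigma2)`,

(the Nakagawa decomposition), and each component's **share of the
explained variance** is its variance over `sigma_f2 + sum(tau)`. The
algebraic inverse `fixed_variance_from_r2()` recovers `sigma_f2` from a
published (marginal, conditional, sum-tau) triple, which is how the
package re-derives explained-variance shares from printed model tables:

```{r r2}
r2_from_components(0, c(28645.2, 5796.5, 2554.0), 30626.0)
tau <- c(turbine_id = 30898.9, bird_id = 5244.8, farm_id = 2481.9)
variance_shares(fixed_variance_from_r2(0.063, 0.613, sum(tau)), tau)
```

Partial-effect grids evaluate the fixed-effects linear predictor over a
focal predictor with other numerics at observed means, factors at
reference or panelled levels, random effects at zero, and delta-method
Wald bands from the coefficient covariance. On rank-deficient designs
(possible in small subsets) aliased columns dropped by the fitting engine
contribute zero, keeping the predictor well defined.

## The synthetic study system

The generator exists so that every stage — and the model stage's ability
to *recover known truth* — is testable without any field download. From a
single integer seed it produces:

* a **landscape**: white noise smoothed by a Gaussian kernel (circular FFT
  convolution) with a 500-m correlation range, rank-quantised to scores
  1–10 at 50-m pixels with equal marginal frequencies;
* two **wind farms** shaped like the study system: 33 turbines with 80-m
  hubs and 40-m blades commissioned over winter 2016–17, and 66 turbines
  with 73-m hubs and 57.5-m blades commissioned through 2018, on jittered
  grids at 350-m spacing with inner/outer labels and uniform base
  elevations;
* **SCADA series**: per-turbine AR(1) latent Gaussian series (persistence
  0.8 per 3-h step) mapped to Weibull(shape 2, scale 8 m s⁻¹) marginal
  wind speeds — typical of exposed Scottish uplands — with rotor speed
  zero below a 3.5 m s⁻¹ cut-in or during random maintenance windows
  (2% of records);
* **telemetry**: a biased correlated random walk. Each step scores 16
  candidate headings by heading persistence (von-Mises-like weight,
  concentration 1.5), preference for high GET scores (weight 0.25 per
  score unit), quadratic attraction to a per-bird activity centre placed
  600 m outside a farm edge, and — only when the nearest turbine is
  operational at that instant — an exponential-decay repulsion
  `beta * exp(-d / rho)` with `beta = 2.5` and `rho = 300` m, optionally
  damped at high wind speed (`wind_coupling = 0.5`), then draws from the
  softmax. Avoidance-as-repulsion is the simplest mechanism that produces
  the qualitative structure of interest (distance up after operation,
  modified by habitat and wind); it is a modelling device, not a claim
  about eagle cognition.

Mean step length is 600 m per 1-minute GSM fix (~10 m s⁻¹), a realistic
cross-country flight speed for a large soaring raptor. This scale matters
statistically as well as biologically: much slower movement makes
consecutive in-buffer fixes so serially dependent that nominal confidence
intervals on the displacement effect undercover, exactly as they would
for oversampled real telemetry. Observed fixes add HDOP-scaled GPS noise
(5 m per HDOP unit horizontally, 1.2× vertically), an HDOP tail beyond
3.5 (12% of fixes), occasional missing (1%) and implausible (0.2%)
altitudes, and a 4% night-time fraction, so every QC rule is exercised;
true positions are retained beside the observed ones as ground truth.
Latitude/longitude come from a fixed affine mock projection centred on
57.15° N so the solar filter is testable. Randomness is partitioned into
per-stage, per-bird substreams derived from the master seed; identical
configurations are byte-identical on disk.

**What the generator does not emulate:** terrain-following flight and
orographic airflow, tag duty-cycle gaps and battery seasonality,
behavioural states (soaring vs directed flight), spatially correlated GPS
error, and collision events. Passing recovery tests therefore shows the
*pipeline* is correct and well calibrated under the assumed data
structure — not that real eagle data satisfy those assumptions.

## Numerical and testing choices

Problem sizes are chosen to make the full validation cheap: recovery
experiments use ten birds and ~10,000 fixes per replicate, with 20
seeded replicates per condition for the null-calibration and
effect-detection checks; descriptive-statistics oracles use brute-force
enumeration (dense sampling along segments, all-pairs nearest-turbine
search, sort-based quantiles) at sizes where brute force is exact enough
to be trusted. Quantiles interpolate linearly between order statistics
(R type 7) throughout, and the "95% range" reported beside distance means
is the empirical 2.5–97.5% data range — with thousands of autocorrelated
records a data range is more honest than a standard error. Degenerate
inputs (empty groups, zero-length segments, all-zero variance
denominators, missing SCADA keys) either produce defined results or
deterministic, typed errors; nothing is silently coerced.

## Known limitations

The 2-D-first closest-approach convention underestimates true 3-D
minimum distance for steeply climbing or descending passes. The phase
contrast treats construction as BEFORE, diluting displacement estimates.
Serial autocorrelation within a bird's track is absorbed only insofar as
the three identity random intercepts capture it; no explicit temporal
correlation structure is fitted, matching the analysis design the package
implements. Wind is joined from the paired turbine only, so spatial wind
gradients within a farm are ignored. The GET raster is consumed as given;
errors in the preference model propagate untested.
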