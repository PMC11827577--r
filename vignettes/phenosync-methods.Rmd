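---
title: "Methods: trophic phenological synchrony with a weather-window dimension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trophic phenological synchrony with a weather-window dimension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spring events in a temperate woodland food web happen in a fixed
ecological order: vegetation greens up (GU), leaf-feeding insects take
their first flight (FF), migrant insectivorous birds arrive (DA).
Climate change shifts each event at a species-specific rate, so the
*gaps* between linked events — not the events themselves — are the
quantity of conservation interest.  `phenosync` implements a complete
chain from raw inputs to interaction indices:

1. reanalysis-style hourly weather → daily TMAX/TMIN/TPPT with a DEM
   lapse-rate correction (`aggregate_daily()`, `regrid_dem_nearest()`,
   `correct_temperature()`);
2. NDVI time series → green-up dates by the half-amplitude method
   (`monthly_max_composite()`, `fill_climatology()`,
   `smooth_and_interpolate()`, `greenup_half_amplitude()`);
3. citizen-science occurrence records → first-event dates per 10 km
   grid cell with inclusion filters (`grid_occurrences()`,
   `first_event()`);
4. a relative sliding time-window regression identifying the critical
   weather window before each event (`best_window()`,
   `randomization_pc()`);
5. the interaction-index family AL, AL′, QAI, WO and IICWM with
   network export (`al_index()` … `build_network()`).

A synthetic-data module (`gen_weather()`, `gen_ndvi()`,
`gen_occurrences()`) generates all inputs with planted ground truth, so
every stage is testable without downloads.

## The indices

For a species pair with the higher trophic level on the left,

* **AL** = (higher-level event day) − (lower-level event day), in days.
  Positive: the consumer follows its resource (synchrony or delayed
  synchrony).  Negative: the consumer precedes it (asynchrony — e.g.
  birds arriving before their prey flies).
* **AL′** = (AL − min)/(max − min) over a pooling group: 0 is total
  asynchrony, 0.5 perfect synchrony, 1 delayed synchrony.  The default
  pool is all AL values of the same trophic pair class (bird–insect,
  insect–vegetation, bird–vegetation) across species pairs and years; a
  per-species-pair pool is available (`pool = "species_pair"`).  The
  pooling definition is genuinely ambiguous in the source method
  ("each group of species within a trophic level"); pooling by pair
  class keeps every AL′ on one common scale within a network layer,
  which is what the network plots require, so it is the default and is
  recorded in the output's `pooling` attribute.
* **QAI** concatenates the A/S labels (A below 0.5, S at or above —
  the boundary is synchronous) of the bird–insect and
  insect–vegetation medians: `SS`, `SA`, `AS`, `AA`.
* **WO** = Σ over {TMIN, TMAX, TPPT} of (bird window-open − insect
  window-open), in days.  Positive (scenario A): bird windows sit
  further in the past and/or insect windows closer to the event.
* **IICWM** = AL / WO, categorised `+` (AL ≥ 0, WO > 0), `*`
  (AL < 0, WO < 0), `-` (the two mixed quadrants).  The value alone is
  ambiguous — `+10/+20` and `−10/−20` are both 0.5 — hence the symbol.
  WO = 0 is refused as an undefined boundary case.  AL = 0 is classed
  with synchrony, consistent with the inclusive 0.5 boundary of the
  qualitative labels.

Missing window-open components in WO are an error by default;
`drop_missing = TRUE` removes the variable from *both* sides so the
composite stays antisymmetric, and records which variables were used.

## The sliding-window engine

Candidate windows are all (open, close) pairs with
0 ≤ close ≤ open ≤ 180 days *before each record's own event date*
(16,471 windows at a 1-day step), inclusive at both ends, with day 0
the event day itself; windows reach into the previous calendar year
when needed.  Temperatures are aggregated by their mean, precipitation
by its sum, both configurable.  Each window's OLS of event day on the
aggregated covariate (k = 3: intercept, slope, variance) is compared by
AICc, `−2·logL + 2k + 2k(k+1)/(n−k−1)` with the Gaussian variance MLE,
against the intercept-only null (k = 2).  Ties are broken toward the
shorter window, then the smaller close; a zero-variance covariate gets
a `+Inf` sentinel so it can never be selected.  The search is a single
vectorised pass over a per-event lag cumulative-sum matrix and agrees
exactly with a brute-force triple loop (tested for max_lag ≤ 10).

Exhaustive search over 16k windows finds "significant" windows in pure
noise — a multiple-testing artefact inherent to the method.  The
guard is **Pc**: event days are permuted across records `n_rand` times
(default 100; tests use 19), the *entire* search is rerun per
permutation (the covariates change too, because windows are relative),
and `pc = (1 + #{permuted ΔAICc ≤ observed ΔAICc})/(1 + n_rand)`.  The
original method's Pc definition is not published in a reproducible
form; this permutation estimate with the add-one correction is our
documented choice.  No significance threshold is hard-coded.

## The synthetic world

Defaults state one fixed world; they are not tuned per test.

* **Weather**: annual sinusoid (mean 9 °C, amplitude 6 °C, peak
  mid-July — a temperate maritime climate), diurnal amplitude 3 °C,
  per-cell AR(1) anomalies (sd 2 °C, lag-1 autocorrelation 0.7,
  synoptic persistence of a few days) shared by TMAX and TMIN, and
  Bernoulli(0.4)-thinned exponential precipitation with mean
  3 mm/day.  The anomalies are the load-bearing choice: weather that
  differs between cells *and fluctuates in time* is what makes a
  planted window identifiable.  A constant spatial offset
  (`cell_offset_sd`, default 0) loads every candidate window equally
  and therefore cannot be localised — with offsets as the dominant
  signal the recovery experiment failed, with AR(1) anomalies it
  recovers the planted window in 20/20 seeds.
* **NDVI**: a double logistic — base 0.35, amplitude 0.45, rising-limb
  steepness 0.15/day centred at the planted green-up day, senescence
  0.10/day centred at day 288 — with Gaussian noise (sd 0.02) and 30 %
  uniformly missing observations (cloud masking).  The rising-limb
  midpoint *is* the planted day by construction, so the half-amplitude
  extraction has an exact truth.
* **Occurrences**: per grid cell the event day solves the
  event-relative fixed point
  `e = intercept + slope·agg(weather, [e−open, e−close]) + ε`,
  ε ~ N(0, residual_sd), damped iteration from the intercept, rounded
  to an integer day.  The residual sits *inside* the fixed point: if it
  is added afterwards the engine measures the covariate at a window
  displaced by the noise, and that errors-in-variables attenuation
  biased recovered slopes ≈ 8 % toward zero.  Sightings start exactly
  at the event day, so the earliest-sighting extraction is exact, and
  every cell gets at least the requested count, so generated sets
  always pass the 3-per-grid / 20-grids filters.

What the generator does *not* emulate: observer effort bias, multiple
broods, spatially correlated anomalies between cells, Landsat
radiometry.  A green recovery test therefore establishes that the
engine inverts its own stated world, not that the method is robust to
citizen-science bias.

## Numerical choices and conventions

* **09 UTC day**: `[09:00, 09:00)` half-open; TMAX and TPPT of the
  window belong to its opening day, TMIN to the following day (a night
  minimum belongs to the morning it precedes).  Windows with fewer
  than 24 hourly values are dropped whole — silent partial aggregation
  would corrupt the extremes.
* **Lapse correction**: the same signed additive term
  `6.49 K/km × (model − DEM elevation)` on TMAX and TMIN; being
  additive per cell it commutes with daily aggregation, so the order
  (correct-then-aggregate vs aggregate-then-correct) is immaterial.
* **Monthly compositing**: the composite keeps the *acquisition date*
  of the retained maximum, the standard maximum-value-composite
  convention.  Pinning composites mid-month biases green-up ≈ 10 days
  early on a rising limb (the month's maximum is its last value);
  measured 54 vs a planted 64.  Mid-month is the fallback when no
  acquisition day exists (climatology-filled months use the 15th).
* **LOESS**: degree 2, tricube weights, default span 0.25, exact
  ("direct") surface, abscissa centred on the series start for
  conditioning.  A span-0.25 window covers ~9 monthly points while the
  green-up transition spans ~1.5 months, so the daily interpolation
  carries an irreducible error: measured RMSE ≈ 0.045 NDVI against a
  noiseless double logistic (the pre-build experiment that fixed the
  0.06 test tolerance).  Consequence: translating a year's NDVI by d
  days shifts the extracted GU by d only up to this phase-dependent
  quantisation; the exact d ± 1 shift property holds at the daily
  half-amplitude step and is asserted there.
* **Half-amplitude**: annual maximum, then the minimum *before* it
  (the rising-limb minimum — a December shoulder below the spring
  baseline must not hijack the amplitude), first crossing of
  min + amplitude/2 located by linear interpolation and rounded.
  Day-of-year is 1-based; leap years keep natural numbering.
* **Gridding**: half-open floor convention,
  `cell = (⌊x/10⌋, ⌊y/10⌋)` in projected km, so boundary points belong
  to exactly one cell.  Event medians use the midpoint convention for
  even counts.
* **Determinism**: every generator restores the caller's RNG state;
  pipeline stages derive per-stage substreams from the run seed; all
  artefacts are UTF-8 CSV with ISO dates and sorted keys, so identical
  config + seed reproduces identical bytes (checked by MD5 in the
  manifest).

## Known limitations

* Grid-level events are treated as independent observations in the
  window regression; spatial autocorrelation between neighbouring
  cells would make ΔAICc anti-conservative on real data (the Pc
  permutation guard helps but does not remove this).
* The monthly NDVI pathway quantises green-up dates (see above);
  sub-weekly GU precision requires denser composites.
* The IICWM inherits the window engine's instability: with weak cues
  the selected window — and hence WO's sign — can flip between years.
  The `+`/`*`/`-` symbols should be read alongside Pc.
* Networks are co-occurrence-in-time summaries; an edge is not
  evidence of a dietary link.  Edge weights (`1 − 2|AL′ − 0.5|` sync,
  `1 − 2·AL′` async) are an explicit display choice, linear in AL′.
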