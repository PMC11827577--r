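# phenosync

Phenological synchrony–asynchrony indices across trophic levels, with
a dynamic meteorological dimension.

## What this is for

In a temperate woodland food web, spring runs in a fixed order:
vegetation green-up (GU) → insect first flight (FF) → migrant-bird
arrival (DA).  Climate change shifts each event at a species-specific
rate, so the *gaps* between linked events are where trophic mismatch
happens.  `phenosync` quantifies those gaps and ties them to the
weather windows that drive each event:

* **AL** — signed day lag between a higher and a lower trophic level
  (`AL = DA − FF`, `DA − GU`, `FF − GU`); positive means the consumer
  follows its resource.
* **AL′** — min–max standardised AL: 0 total asynchrony, 0.5 perfect
  synchrony, 1 delayed synchrony.
* **QAI** — qualitative two-letter index (`SS`, `SA`, `AS`, `AA`)
  concatenating the bird–insect and insect–vegetation labels.
* **WO** — Σ over TMIN/TMAX/TPPT of bird-minus-insect window-open
  days, from a relative sliding time-window regression (all windows
  0–180 days before each record's own event, exhaustive OLS + AICc
  selection with a permutation significance Pc).
* **IICWM** — `AL / WO` with a three-symbol categorisation (`+`, `-`,
  `*`) combining synchrony state and window-movement scenario.

The package also ships the upstream machinery: 09 UTC daily weather
aggregation with a 6.49 K/km DEM lapse correction, NDVI green-up
extraction (monthly-max composite → climatology fill → LOESS → half
amplitude), occurrence gridding with the 3-sightings/20-grids filters,
trophic-network export, a CLI, and a synthetic-data generator with
planted ground truth so the whole chain is testable offline.

## Worked example

Simulate a world in which minimum temperature averaged over days
50–25 before the event advances it by 2 days per °C, then recover that
window blind:

```r
library(phenosync)

# 1. synthetic weather grid and occurrences with a planted window
cfg <- weather_sim_config(n_cells = 40, date_start = "2014-06-01",
                          date_end = "2015-12-31", seed = 1)
wx  <- gen_weather(cfg, "daily")
pw  <- planted_window("TMIN", open_days = 50, close_days = 25,
                      slope = -2, intercept = 120, residual_sd = 1)
occ <- gen_occurrences(wx, pw, n_grids = 40, sightings_per_grid = 3,
                       year = 2015, seed = 2)

# 2. grid the records, apply the inclusion filters, summarise
events <- first_event(grid_occurrences(occ$data),
                      min_per_grid = 3, min_grids = 20)$events
summarize_events(events)
#>   species year  n median q25 q75 min max
#> 1     SPX 2015 40    114 113 115 108 118

# 3. exhaustive relative window search (truth: open 50, close 25)
ev <- data.frame(species = "SPX", year = 2015,
                 cell_id = occ$truth$events$cell_id,
                 event_day = occ$truth$events$event_day)
best_window(ev, wx$data, "TMIN")
#> window_fit: TMIN mean window open 46 close 28 | slope -2.009 dAICc -52.152 n 40
randomization_pc(ev, wx$data, "TMIN", n_rand = 19, seed = 3)$pc
#> [1] 0.05
```

The selected window (46–28 days before the event, slope −2.01 days/°C)
overlaps the planted 50–25 window and recovers the planted slope; the
permutation Pc of 0.05 (= 1/20, the observed fit beat all 19
permutations) marks it significant.

Index arithmetic and the packaged case-study table:

```r
iicwm(al = 10, wo = 20)       # synchronous pair, scenario A
#>   value category
#> 1   0.5        +

t <- tally_classifications()  # packaged 90-row bird-insect table
t$categories
#>  +  -  *
#> 12 42 36
t$fully_synchronous
#> [1] 17
```

A full pipeline run (simulate → prep-weather → extract-greenup →
extract-events → windows → indices → network, with a byte-stable
manifest) is one call:

```r
run_pipeline(run_config(seed = 1, out = "run1"))
```

or from the shell via the CLI launcher:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/phenosync.R", package="phenosync"))') \
    run --seed 1 --out run1
```

## Layout

* `R/` — implementation; `vignettes/phenosync-methods.Rmd` — model,
  conventions, synthetic-world rationale, known limitations.
* `inst/extdata/` — packaged species roster (30 species/groups) and
  the 90-row bird–insect classification table.
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles in `helper-oracles.R`.
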