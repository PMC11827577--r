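# Independent brute-force oracles, written as plain loops and kept
# free of the package's vectorised code paths.

# Exhaustive nested-loop window search: for every (open, close) pair,
# build the covariate day by day, fit lm(), compute AICc by hand, keep
# the minimum (ties to the shorter window then smaller close).
bf_best_window <- function(events, weather, variable, statistic,
                           max_lag) {
  col <- c(TMIN = "tmin", TMAX = "tmax", TPPT = "tppt")[[variable]]
  key <- paste(weather$cell_id, weather$date)
  best <- NULL
  for (open in 0:max_lag) {
    for (close in 0:open) {
      x <- numeric(nrow(events))
      for (i in seq_len(nrow(events))) {
        d <- as.Date(paste0(events$year[i], "-01-01")) +
          events$event_day[i] - 1
        days <- seq(d - open, d - close, by = "day")
        vals <- weather[[col]][match(paste(events$cell_id[i], days), key)]
        x[i] <- if (statistic == "mean") mean(vals) else sum(vals)
      }
      if (stats::var(x) == 0) next
      f <- stats::lm(events$event_day ~ x)
      n <- nrow(events)
      rss <- sum(stats::resid(f)^2)
      ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
      a <- -2 * ll + 2 * 3 + 2 * 3 * 4 / (n - 4)
      better <- is.null(best) ||
        a < best$aicc - 1e-12 ||
        (abs(a - best$aicc) <= 1e-12 &&
           (open - close < best$open - best$close ||
              (open - close == best$open - best$close &&
                 close < best$close)))
      if (better)
        best <- list(open = open, close = close, aicc = a,
                     slope = unname(stats::coef(f)[2]))
    }
  }
  best
}

# Events + weather with a planted window, shared by several tests.
make_planted_world <- function(seed, n_grids = 40, open = 50, close = 25,
                               slope = -2, intercept = 120,
                               residual_sd = 1, variable = "TMIN") {
  cfg <- weather_sim_config(n_grids, "2014-06-01", "2015-12-31",
                            seed = seed)
  w <- gen_weather(cfg, "daily")
  pw <- planted_window(variable, open, close, slope, intercept,
                       residual_sd)
  occ <- gen_occurrences(w, pw, n_grids = n_grids,
                         sightings_per_grid = 3, year = 2015,
                         seed = seed + 500)
  list(weather = w,
       events = data.frame(species = "SPX", year = 2015,
                           cell_id = occ$truth$events$cell_id,
                           event_day = occ$truth$events$event_day),
       occurrences = occ)
}

# Three years of synthetic NDVI for one polygon.
make_ndvi_years <- function(green_up_day = 64, years = 2013:2015,
                            noise_sd = 0, missing_rate = 0.3,
                            seed_base = 0) {
  do.call(rbind, lapply(years, function(y)
    gen_ndvi(green_up_day, noise_sd = noise_sd,
             missing_rate = missing_rate, seed = y + seed_base,
             year = y)$data))
}

# Evaluate expr under a local seed without touching the global stream.
with_seed2 <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Tiny constant-weather table.
make_constant_weather <- function(cells = 1:3, dates, tmin = 5,
                                  tmax = 10, tppt = 0) {
  g <- expand.grid(cell_id = cells, date = dates)
  data.frame(cell_id = g$cell_id, date = g$date, tmax = tmax,
             tmin = tmin, tppt = tppt)
}
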