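#' Configuration for the synthetic weather generator
#'
#' Describes a gridded weather simulation on an abstract projected grid:
#' integer cell ids laid out in a row of `cell_size` km squares, an
#' annual temperature sinusoid (peak in mid July), an optional diurnal
#' sinusoid (peak at 15:00 UTC), per-cell AR(1) temperature anomalies
#' emulating synoptic weather systems that persist for a few days, and
#' exponential wet-day precipitation.  The anomalies are independent
#' between cells and shared by day and night temperature; their
#' marginal standard deviation is `noise_sd` and their lag-1
#' autocorrelation `noise_ar1`.  Because anomalies fluctuate in time,
#' the weather aggregated over different day ranges differs between
#' cells — this temporal localisation is what makes critical windows
#' identifiable downstream.  Optional constant per-cell offsets
#' (`cell_offset_sd`, default 0) add a persistent spatial gradient;
#' note a constant offset loads every candidate window equally and so
#' weakens window identifiability.
#'
#' @param n_cells number of grid cells (positive integer).
#' @param date_start,date_end first and last simulated calendar date.
#' @param mean_temp_annual annual mean temperature, degrees C.
#' @param seasonal_amplitude half-range of the annual sinusoid, degrees C.
#' @param diurnal_amplitude half-range of the day/night sinusoid, degrees C.
#' @param precip_rate expected precipitation, mm/day.
#' @param noise_sd marginal standard deviation of the AR(1)
#'   temperature anomaly, degrees C.
#' @param noise_ar1 lag-1 autocorrelation of the anomaly, in `[0, 1)`.
#' @param cell_offset_sd standard deviation of the per-cell constant
#'   temperature offset, degrees C.
#' @param wet_prob daily wet-day probability of the Bernoulli thinning.
#' @param cell_size_km grid-cell edge length, km.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#' @return an object of class `weather_sim_config`.
#' @export
weather_sim_config <- function(n_cells,
                               date_start, date_end,
                               mean_temp_annual = 9,
                               seasonal_amplitude = 6,
                               diurnal_amplitude = 3,
                               precip_rate = 3,
                               noise_sd = 2,
                               noise_ar1 = 0.7,
                               cell_offset_sd = 0,
                               wet_prob = 0.4,
                               cell_size_km = 10,
                               seed = 1L) {
  date_start <- as.Date(date_start); date_end <- as.Date(date_end)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stopf("invalid config: n_cells must be a positive integer, got %s",
          deparse(n_cells))
  if (is.na(date_start) || is.na(date_end) || date_start >= date_end)
    stopf("invalid config: date_start must precede date_end")
  if (seasonal_amplitude < 0 || diurnal_amplitude < 0 || noise_sd < 0 ||
      cell_offset_sd < 0)
    stopf("invalid config: amplitudes and noise_sd must be non-negative")
  if (noise_ar1 < 0 || noise_ar1 >= 1)
    stopf("invalid config: noise_ar1 must be in [0, 1)")
  if (precip_rate < 0 || wet_prob <= 0 || wet_prob > 1)
    stopf("invalid config: precip_rate >= 0 and 0 < wet_prob <= 1 required")
  structure(list(n_cells = as.integer(n_cells),
                 date_start = date_start, date_end = date_end,
                 mean_temp_annual = mean_temp_annual,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude,
                 precip_rate = precip_rate, noise_sd = noise_sd,
                 noise_ar1 = noise_ar1,
                 cell_offset_sd = cell_offset_sd, wet_prob = wet_prob,
                 cell_size_km = cell_size_km, seed = as.integer(seed)),
            class = "weather_sim_config")
}

# Annual temperature sinusoid evaluated at a fractional day-of-year.
annual_sinusoid <- function(config, day_frac) {
  config$mean_temp_annual +
    config$seasonal_amplitude * cos(2 * pi * (day_frac - 197) / 365.25)
}

#' Generate synthetic gridded weather
#'
#' Simulates per-cell hourly or daily weather from a
#' [weather_sim_config()].  Daily output follows the TMAX/TMIN/TPPT
#' convention consumed by the analysis stages; hourly output feeds
#' [aggregate_daily()].  Precipitation is Bernoulli-thinned exponential:
#' wet days occur with probability `wet_prob` and carry an
#' Exponential(mean = precip_rate / wet_prob) amount, so the expected
#' daily total is `precip_rate`.
#'
#' @param config a [weather_sim_config()].
#' @param granularity `"daily"` or `"hourly"`.
#' @return a list with elements `data` (the weather table), `cells`
#'   (cell id, centre coordinates in km, model orography elevation in m,
#'   and the planted per-cell temperature offset) and `config` (the
#'   ground truth used).
#' @export
gen_weather <- function(config, granularity = c("daily", "hourly")) {
  stopifnot(inherits(config, "weather_sim_config"))
  granularity <- match.arg(granularity)
  with_seed(config$seed, {
    cs <- config$cell_size_km
    cells <- data.frame(
      cell_id = seq_len(config$n_cells),
      x_km = (seq_len(config$n_cells) - 1) * cs + cs / 2,
      y_km = cs / 2,
      model_elev = round(stats::runif(config$n_cells, 20, 320), 1),
      temp_offset = stats::rnorm(config$n_cells, 0, config$cell_offset_sd))
    dates <- seq(config$date_start, config$date_end, by = "day")
    nd <- length(dates)
    # per-cell stationary AR(1) anomaly, marginal sd = noise_sd,
    # shared by day and night temperature (synoptic systems)
    anom <- matrix(0, nd, config$n_cells)
    if (config$noise_sd > 0) {
      rho <- config$noise_ar1
      innov_sd <- config$noise_sd * sqrt(1 - rho^2)
      anom[1, ] <- stats::rnorm(config$n_cells, 0, config$noise_sd)
      if (nd > 1) for (t in 2:nd)
        anom[t, ] <- rho * anom[t - 1, ] +
          stats::rnorm(config$n_cells, 0, innov_sd)
    }
    if (granularity == "daily") {
      df <- data.table::CJ(cell_id = cells$cell_id, date = dates)
      day_frac <- doy(df$date)
      a <- anom[cbind(match(df$date, dates), df$cell_id)]
      base <- annual_sinusoid(config, day_frac) +
        cells$temp_offset[df$cell_id] + a
      hi <- base + config$diurnal_amplitude
      lo <- base - config$diurnal_amplitude
      wet <- stats::rbinom(nrow(df), 1L, config$wet_prob)
      amt <- stats::rexp(nrow(df),
                         rate = config$wet_prob / max(config$precip_rate,
                                                      .Machine$double.eps))
      out <- data.frame(cell_id = df$cell_id, date = df$date,
                        tmax = pmax(hi, lo), tmin = pmin(hi, lo),
                        tppt = if (config$precip_rate > 0) wet * amt else 0)
      out <- out[order(out$cell_id, out$date), ]
    } else {
      stamps <- seq(as.POSIXct(paste(config$date_start, "00:00:00"),
                               tz = "UTC"),
                    as.POSIXct(paste(config$date_end, "23:00:00"),
                               tz = "UTC"),
                    by = "hour")
      df <- data.table::CJ(cell_id = cells$cell_id, timestamp = stamps)
      stamp_day <- as.Date(df$timestamp, tz = "UTC")
      hour <- as.integer(format(df$timestamp, "%H", tz = "UTC"))
      day_frac <- doy(stamp_day) + hour / 24
      a <- anom[cbind(match(stamp_day, dates), df$cell_id)]
      temp <- annual_sinusoid(config, day_frac) +
        cells$temp_offset[df$cell_id] + a +
        config$diurnal_amplitude * cos(2 * pi * (hour - 15) / 24)
      # hourly wet probability chosen so the daily total's expectation
      # is precip_rate
      p_h <- min(1, config$wet_prob / 4)
      wet <- stats::rbinom(nrow(df), 1L, p_h)
      amt <- stats::rexp(nrow(df),
                         rate = 24 * p_h / max(config$precip_rate,
                                               .Machine$double.eps))
      out <- data.frame(cell_id = df$cell_id, timestamp = df$timestamp,
                        temp_c = temp,
                        precip_mm = if (config$precip_rate > 0) wet * amt
                                    else 0)
      out <- out[order(out$cell_id, out$timestamp), ]
    }
    rownames(out) <- NULL
    list(data = out, cells = cells, config = config)
  })
}

#' Generate a synthetic annual NDVI series with planted green-up
#'
#' The curve is a double logistic: a rising limb centred exactly at
#' `green_up_day` (so the true half-amplitude crossing is
#' `green_up_day` by construction) times a mirrored senescence limb
#' centred at `senescence_day`.  Gaussian noise is added and
#' observations are dropped uniformly at random with probability
#' `missing_rate`, emulating cloud-masked satellite series.
#'
#' @param green_up_day day-of-year of the planted half-amplitude
#'   crossing.
#' @param base NDVI winter baseline in `[0, 1]`.
#' @param amplitude rise of the summer plateau above `base`;
#'   `base + amplitude` must stay within `[0, 1]`.
#' @param steepness logistic slope of the rising limb, 1/days.
#' @param noise_sd Gaussian observation noise, NDVI units.
#' @param missing_rate fraction of days dropped, in `[0, 1)`.
#' @param seed integer seed.
#' @param year calendar year simulated.
#' @param polygon_id identifier written into the output.
#' @param senescence_day,senescence_steepness centre and slope of the
#'   autumn decline.
#' @return list with `data` (polygon_id, date, ndvi) and `truth`
#'   (the planted parameters).
#' @export
gen_ndvi <- function(green_up_day, base = 0.35, amplitude = 0.45,
                     steepness = 0.15, noise_sd = 0.02,
                     missing_rate = 0.3, seed = 1L, year = 2015L,
                     polygon_id = "POLY1",
                     senescence_day = 288, senescence_steepness = 0.10) {
  if (amplitude <= 0) stopf("invalid config: amplitude must be positive")
  if (base < 0 || base + amplitude > 1)
    stopf("invalid config: need 0 <= base and base + amplitude <= 1")
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("invalid config: missing_rate must be in [0, 1)")
  days <- seq_len(if (is_leap(year)) 366L else 365L)
  curve <- ndvi_double_logistic(days, green_up_day, base, amplitude,
                                steepness, senescence_day,
                                senescence_steepness)
  with_seed(seed, {
    vals <- curve + stats::rnorm(length(days), 0, noise_sd)
    keep <- stats::runif(length(days)) >= missing_rate
    data <- data.frame(polygon_id = polygon_id,
                       date = date_from_doy(year, days[keep]),
                       ndvi = pmin(1, pmax(-1, vals[keep])))
    list(data = data,
         truth = list(green_up_day = green_up_day, base = base,
                      amplitude = amplitude, steepness = steepness,
                      senescence_day = senescence_day,
                      senescence_steepness = senescence_steepness,
                      noise_sd = noise_sd, missing_rate = missing_rate,
                      year = year))
  })
}

is_leap <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

# Noiseless double-logistic NDVI curve; rising-limb midpoint sits at
# green_up_day (the senescence factor is ~1 there for any reasonable
# separation of the two limbs).
ndvi_double_logistic <- function(day, green_up_day, base, amplitude,
                                 steepness, senescence_day,
                                 senescence_steepness) {
  base + amplitude *
    stats::plogis(steepness * (day - green_up_day)) *
    stats::plogis(-senescence_steepness * (day - senescence_day))
}

#' Planted critical weather window
#'
#' Ground truth for the sliding-window engine: event dates are a linear
#' function of the weather aggregated over a window measured backwards
#' from each cell's own event date, the same event-relative convention
#' used by the analysis, plus Gaussian noise.
#'
#' @param variable one of `"TMIN"`, `"TMAX"`, `"TPPT"`.
#' @param open_days,close_days window bounds in days before the event;
#'   `open_days >= close_days >= 0` and `open_days <= 180`.
#' @param slope days of event shift per unit of aggregated weather.
#' @param intercept baseline day-of-year.
#' @param residual_sd Gaussian residual on the event day, days.
#' @param statistic aggregate statistic; defaults to mean for
#'   temperatures and sum for precipitation.
#' @return an object of class `planted_window`.
#' @export
planted_window <- function(variable = c("TMIN", "TMAX", "TPPT"),
                           open_days, close_days, slope, intercept,
                           residual_sd = 1,
                           statistic = NULL) {
  variable <- match.arg(variable)
  if (close_days < 0 || open_days < close_days || open_days > 180)
    stopf("invalid window: need 0 <= close_days <= open_days <= 180")
  if (residual_sd < 0) stopf("invalid window: residual_sd must be >= 0")
  statistic <- statistic %||% default_statistic(variable)
  structure(list(variable = variable, open_days = as.integer(open_days),
                 close_days = as.integer(close_days), slope = slope,
                 intercept = intercept, residual_sd = residual_sd,
                 statistic = statistic),
            class = "planted_window")
}

default_statistic <- function(variable) {
  if (variable == "TPPT") "sum" else "mean"
}

#' Generate occurrence records whose event dates follow a planted window
#'
#' For each grid cell the true event day solves the event-relative
#' fixed point `e = intercept + slope * agg(weather, [e-open, e-close])`
#' (damped iteration from `intercept`), then Gaussian residual noise is
#' added and the day rounded.  Sightings are placed on and after the
#' event day so the earliest sighting in the cell equals the event day,
#' and every cell receives at least `sightings_per_grid` records —
#' generated sets with `n_grids >= 20` and `sightings_per_grid >= 3`
#' always survive the downstream inclusion filters.
#'
#' @param weather daily weather as returned by `gen_weather(...)$data`
#'   (or the full `gen_weather()` result).
#' @param window a [planted_window()].
#' @param n_grids number of grid cells to populate.
#' @param sightings_per_grid records per cell (>= 1).
#' @param year calendar year of the events.
#' @param seed integer seed.
#' @param species species code written into the records.
#' @param cells optional cell-centre table (cell_id, x_km, y_km); taken
#'   from the `gen_weather()` result when `weather` is that list.
#' @param cell_size_km grid-cell size used to jitter sighting
#'   coordinates inside each cell.
#' @return list with `data` (species, date, x_km, y_km), `truth`
#'   (planted window plus the per-cell true event days) and `year`.
#' @export
gen_occurrences <- function(weather, window, n_grids = 25L,
                            sightings_per_grid = 3L, year, seed = 1L,
                            species = "SPX", cells = NULL,
                            cell_size_km = 10) {
  stopifnot(inherits(window, "planted_window"))
  if (is.list(weather) && !is.data.frame(weather)) {
    cells <- cells %||% weather$cells
    weather <- weather$data
  }
  assert_cols(weather, c("cell_id", "date"), "weather")
  col <- variable_column(window$variable)
  assert_cols(weather, col, "weather")
  ids <- sort(unique(weather$cell_id))
  if (length(ids) < n_grids)
    stopf("weather has %d cells but n_grids = %d", length(ids), n_grids)
  ids <- ids[seq_len(n_grids)]
  if (is.null(cells))
    cells <- data.frame(cell_id = ids,
                        x_km = (match(ids, ids) - 1) * cell_size_km +
                          cell_size_km / 2,
                        y_km = cell_size_km / 2)

  wtab <- data.table::as.data.table(weather)
  data.table::setkeyv(wtab, c("cell_id", "date"))
  agg_fun <- match.fun(window$statistic)

  with_seed(seed, {
    recs <- vector("list", n_grids)
    true_events <- integer(n_grids)
    for (i in seq_len(n_grids)) {
      cid <- ids[i]
      w <- wtab[list(cid)]
      # the residual enters the fixed point, so the realised event day
      # satisfies e = intercept + slope * agg(window at e) + eps up to
      # integer rounding (no errors-in-variables attenuation downstream)
      eps <- stats::rnorm(1, 0, window$residual_sd)
      e <- window$intercept + eps
      for (iter in seq_len(40L)) {
        d <- date_from_doy(year, round(e))
        span <- seq(d - window$open_days, d - window$close_days, by = "day")
        vals <- w[[col]][match(span, w$date)]
        if (anyNA(vals)) {
          first_missing <- span[which(is.na(vals))[1]]
          stopf("weather coverage error: cell %s needs %s for an event near day %d",
                as.character(cid), format(first_missing), round(e))
        }
        e_new <- window$intercept + window$slope * agg_fun(vals) + eps
        if (abs(e_new - e) < 0.25) { e <- e_new; break }
        e <- e + 0.7 * (e_new - e)  # damped to guarantee convergence
      }
      ev <- as.integer(round(e))
      true_events[i] <- ev
      offs <- c(0L, sort(sample.int(21L, sightings_per_grid - 1L,
                                    replace = TRUE)))
      ctr <- cells[match(cid, cells$cell_id), ]
      recs[[i]] <- data.frame(
        species = species,
        date = date_from_doy(year, ev) + offs,
        x_km = ctr$x_km + stats::runif(length(offs), -cell_size_km / 2,
                                       cell_size_km / 2 - 1e-9),
        y_km = ctr$y_km + stats::runif(length(offs), -cell_size_km / 2,
                                       cell_size_km / 2 - 1e-9))
    }
    list(data = do.call(rbind, recs),
         truth = list(window = window,
                      events = data.frame(cell_id = ids,
                                          event_day = true_events)),
         year = year)
  })
}

#' Generate scattered DEM sample points around simulated grid cells
#'
#' Emits a plain point table (x_km, y_km, elev_m) covering the cell
#' centres, for exercising nearest-neighbour DEM regridding.  True cell
#' elevations are the model orography plus a planted bias, so the
#' regridding + lapse-correction path has known ground truth.
#'
#' @param cells cell table from [gen_weather()].
#' @param points_per_cell DEM samples scattered around each centre.
#' @param bias_m planted mean offset of DEM elevation above the model
#'   orography, metres.
#' @param jitter_km spatial scatter of the samples.
#' @param seed integer seed.
#' @return list with `data` (x_km, y_km, elev_m) and `truth` (per-cell
#'   dem elevation of the sample nearest each centre).
#' @export
gen_dem <- function(cells, points_per_cell = 5L, bias_m = 60,
                    jitter_km = 3, seed = 1L) {
  assert_cols(cells, c("cell_id", "x_km", "y_km", "model_elev"), "cells")
  with_seed(seed, {
    n <- nrow(cells) * points_per_cell
    idx <- rep(seq_len(nrow(cells)), each = points_per_cell)
    pts <- data.frame(
      x_km = cells$x_km[idx] + stats::rnorm(n, 0, jitter_km),
      y_km = cells$y_km[idx] + stats::rnorm(n, 0, jitter_km),
      elev_m = round(cells$model_elev[idx] + bias_m +
                       stats::rnorm(n, 0, 15), 1))
    truth <- regrid_dem_nearest(pts, cells)
    list(data = pts, truth = truth)
  })
}
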