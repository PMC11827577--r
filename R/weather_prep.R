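# Daily aggregation to the 09 UTC convention and DEM lapse-rate
# correction of reanalysis-style gridded temperatures.

#' Aggregate hourly weather to daily TMAX/TMIN/TPPT
#'
#' Uses the 09 UTC observational day: precipitation totals and maximum
#' temperature over `[D 09:00, D+1 09:00)` are assigned to day `D`,
#' while the minimum temperature over the same interval is assigned to
#' the following day `D+1` (a night minimum belongs to the morning it
#' precedes).  The window is half-open at the right boundary.  Windows
#' with fewer than 24 hourly values are dropped entirely rather than
#' partially aggregated.
#'
#' @param hourly data.frame with columns `cell_id`, `timestamp`
#'   (POSIXct UTC or ISO-8601 strings), `temp_c`, `precip_mm`.
#' @return a daily data.frame with columns `cell_id`, `date`, `tmax`,
#'   `tmin`, `tppt`; `NA` marks components whose window was incomplete
#'   (e.g. the first day's `tmin`).
#' @export
aggregate_daily <- function(hourly) {
  assert_cols(hourly, c("cell_id", "timestamp", "temp_c", "precip_mm"),
              "hourly")
  ts <- hourly$timestamp
  if (is.character(ts))
    ts <- as.POSIXct(ts, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (!inherits(ts, "POSIXct"))
    stopf("input contract: timestamps must be POSIXct or ISO-8601 strings")
  tzone <- attr(ts, "tzone") %||% ""
  if (!tzone %in% c("UTC", "GMT"))
    stopf("input contract: timestamps must be UTC, got timezone '%s'", tzone)
  if (anyNA(ts)) stopf("input contract: unparseable timestamps present")

  dt <- data.table::data.table(cell_id = hourly$cell_id, ts = ts,
                               temp_c = hourly$temp_c,
                               precip_mm = hourly$precip_mm)
  if (dt[, any(diff(as.numeric(ts)) < 0), by = "cell_id"][, any(V1)])
    stopf("input contract: timestamps must be sorted within each cell")

  # observational day: the 09 UTC window an hour falls in, labelled by
  # the day the window opened
  dt[, obs_day := as.Date(ts - 9 * 3600, tz = "UTC")]
  agg <- dt[, list(n_hours = .N,
                   wmax = max(temp_c), wmin = min(temp_c),
                   wppt = sum(precip_mm)),
            by = c("cell_id", "obs_day")]
  agg <- agg[agg$n_hours >= 24L]
  if (nrow(agg) == 0L)
    return(data.frame(cell_id = dt$cell_id[0], date = as.Date(character()),
                      tmax = numeric(), tmin = numeric(), tppt = numeric()))
  maxes <- agg[, list(cell_id, date = obs_day, tmax = wmax, tppt = wppt)]
  mins <- agg[, list(cell_id, date = obs_day + 1L, tmin = wmin)]
  out <- merge(maxes, mins, by = c("cell_id", "date"), all = TRUE)
  data.table::setorderv(out, c("cell_id", "date"))
  as.data.frame(out[, list(cell_id, date, tmax, tmin, tppt)])
}

#' Assign each grid cell the elevation of its nearest DEM sample
#'
#' Plain nearest-neighbour regridding of DEM points onto cell centres.
#' Equidistant samples are resolved to the smallest sample index, so the
#' assignment is deterministic.
#'
#' @param dem data.frame of DEM samples with columns `x_km`, `y_km`,
#'   `elev_m`.
#' @param grid data.frame of cell centres with columns `cell_id`,
#'   `x_km`, `y_km`.
#' @param max_dist_km optional coverage radius; a cell whose nearest
#'   sample is farther away triggers a coverage error listing the cells.
#' @return `grid` with an added `dem_elev` column.
#' @export
regrid_dem_nearest <- function(dem, grid, max_dist_km = Inf) {
  assert_cols(dem, c("x_km", "y_km", "elev_m"), "dem")
  assert_cols(grid, c("cell_id", "x_km", "y_km"), "grid")
  if (nrow(dem) == 0L) stopf("dem table is empty")
  d2 <- outer(grid$x_km, dem$x_km, "-")^2 + outer(grid$y_km, dem$y_km, "-")^2
  nearest <- apply(d2, 1L, which.min)   # which.min takes the first tie
  dist <- sqrt(d2[cbind(seq_len(nrow(grid)), nearest)])
  if (any(dist > max_dist_km)) {
    bad <- grid$cell_id[dist > max_dist_km]
    stopf("DEM coverage error: cell(s) %s beyond %g km of any sample",
          paste(bad, collapse = ", "), max_dist_km)
  }
  grid$dem_elev <- dem$elev_m[nearest]
  grid
}

#' Lapse-rate correction of daily temperatures for orography mismatch
#'
#' Reanalysis temperatures refer to the model orography; where the true
#' (DEM) surface is lower the model runs cold and vice versa.  Both
#' `tmax` and `tmin` receive the same signed additive correction
#' `lapse_rate * (model_elev - dem_elev) / 1000`; precipitation is
#' untouched.  The default 6.49 K/km is the ICAO standard-atmosphere
#' lapse rate.  Applying the correction twice with the two elevations
#' swapped recovers the input, and `tmax - tmin` is invariant.
#'
#' @param daily daily weather data.frame with `tmax`, `tmin` and the
#'   per-row elevations `model_elev`, `dem_elev` (metres); alternatively
#'   supply `elev` to merge elevations by `cell_id`.
#' @param lapse_rate K per km of height difference.
#' @param elev optional per-cell table (`cell_id`, `model_elev`,
#'   `dem_elev`) merged into `daily` first.
#' @return `daily` with corrected temperatures.
#' @export
correct_temperature <- function(daily, lapse_rate = 6.49, elev = NULL) {
  assert_cols(daily, c("cell_id", "tmax", "tmin"), "daily")
  if (!is.null(elev)) {
    assert_cols(elev, c("cell_id", "model_elev", "dem_elev"), "elev")
    daily$model_elev <- NULL; daily$dem_elev <- NULL
    daily <- merge(daily, elev[, c("cell_id", "model_elev", "dem_elev")],
                   by = "cell_id", all.x = TRUE, sort = FALSE)
  }
  assert_cols(daily, c("model_elev", "dem_elev"), "daily")
  bad <- unique(daily$cell_id[is.na(daily$model_elev) |
                                is.na(daily$dem_elev)])
  if (length(bad))
    stopf("missing elevation for cell(s): %s", paste(bad, collapse = ", "))
  corr <- lapse_rate * (daily$model_elev - daily$dem_elev) / 1000
  daily$tmax <- daily$tmax + corr
  daily$tmin <- daily$tmin + corr
  daily
}
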