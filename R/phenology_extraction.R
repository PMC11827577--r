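# Green-up extraction from NDVI and first-event extraction from
# gridded occurrence records.

#' Composite an NDVI series to monthly maxima
#'
#' Maximum-value compositing suppresses cloud- and atmosphere-induced
#' dropouts: the monthly value is the max of whatever observations the
#' month has.  Months with no observations stay absent from the output
#' (absence is never coded as zero).
#'
#' @param series data.frame with columns `polygon_id`, `date`, `ndvi`
#'   (NA allowed).
#' @return data.frame `polygon_id`, `year`, `month`, `ndvi`, `day`
#'   with one row per observed polygon-month; `day` is the
#'   day-of-month of the retained (maximum) observation, the
#'   acquisition date the composite keeps for interpolation.
#' @export
monthly_max_composite <- function(series) {
  assert_cols(series, c("polygon_id", "date", "ndvi"), "series")
  series <- series[!is.na(series$ndvi), , drop = FALSE]
  if (nrow(series) == 0L) stopf("empty NDVI series: nothing to composite")
  dt <- data.table::as.data.table(series)
  dt[, `:=`(year = as.integer(format(date, "%Y")),
            mon = as.integer(format(date, "%m")))]
  out <- dt[, list(ndvi = max(ndvi),
                   day = as.integer(format(date[which.max(ndvi)], "%d"))),
            by = c("polygon_id", "year", "mon")]
  data.table::setnames(out, "mon", "month")
  data.table::setorderv(out, c("polygon_id", "year", "month"))
  as.data.frame(out)
}

#' Fill monthly NDVI gaps with the cross-year climatology
#'
#' A month missing in year y is replaced by the mean of that calendar
#' month over all years in which it was observed; observed values are
#' untouched.  Needs at least two years so a climatology exists.
#'
#' @param monthly output of [monthly_max_composite()].
#' @return a gap-free monthly data.frame covering every (year, month)
#'   in each polygon's year range, with a logical `filled` column.
#' @export
fill_climatology <- function(monthly) {
  assert_cols(monthly, c("polygon_id", "year", "month", "ndvi"), "monthly")
  parts <- lapply(split(monthly, monthly$polygon_id), function(m) {
    yrs <- seq(min(m$year), max(m$year))
    full <- expand.grid(year = yrs, month = 1:12)
    full <- full[order(full$year, full$month), ]
    full$polygon_id <- m$polygon_id[1]
    if (!"day" %in% names(m)) m$day <- 15L
    full <- merge(full, m[, c("year", "month", "ndvi", "day")],
                  by = c("year", "month"), all.x = TRUE)
    full <- full[order(full$year, full$month), ]  # merge sorts as text
    clim <- tapply(m$ndvi, m$month, mean)
    gap <- is.na(full$ndvi)
    unfillable <- setdiff(unique(full$month[gap]),
                          as.integer(names(clim)))
    if (length(unfillable))
      stopf("unfillable gap: polygon %s has no observation of month(s) %s in any year",
            m$polygon_id[1], paste(sort(unfillable), collapse = ", "))
    full$ndvi[gap] <- clim[as.character(full$month[gap])]
    full$day[gap] <- 15L                 # climatology values sit mid-month
    full$filled <- gap
    full[, c("polygon_id", "year", "month", "day", "ndvi", "filled")]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' LOESS-smooth a monthly NDVI series and interpolate to daily values
#'
#' Monthly composites are placed at their retained acquisition date
#' (`day` column; mid-month when absent), smoothed
#' with locally weighted quadratic regression (tricube weights), and
#' the fit is evaluated at every day spanned by the series.  Smoothing
#' removes single-month spikes; interpolation gives the daily
#' resolution the half-amplitude green-up extraction needs.
#'
#' @param monthly gap-free monthly data.frame (see
#'   [fill_climatology()]), single polygon or several.
#' @param span LOESS span fraction; the local neighbourhood is
#'   `span * n` points and must hold at least 4.
#' @return data.frame `polygon_id`, `date`, `ndvi` with one row per day.
#' @export
smooth_and_interpolate <- function(monthly, span = 0.25) {
  assert_cols(monthly, c("polygon_id", "year", "month", "ndvi"), "monthly")
  parts <- lapply(split(monthly, monthly$polygon_id), function(m) {
    if (nrow(m) < 8L)
      stopf("polygon %s: %d monthly points, need >= 8 for local regression",
            m$polygon_id[1], nrow(m))
    if (span * nrow(m) < 4) {
      feas <- ceiling(400 / nrow(m)) / 100
      stopf("span %.3f too small for %d points (local window < 4 points); smallest feasible span is about %.2f",
            span, nrow(m), feas)
    }
    m <- m[order(m$year, m$month), ]
    dom <- if ("day" %in% names(m)) m$day else rep(15L, nrow(m))
    t_abs <- as.numeric(as.Date(sprintf("%d-%02d-%02d", m$year,
                                        m$month, dom)))
    t_rel <- t_abs - t_abs[1]            # centred for conditioning
    fit <- stats::loess(ndvi ~ t_rel, data = data.frame(ndvi = m$ndvi,
                                                        t_rel = t_rel),
                        span = span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    days <- seq(0, t_rel[length(t_rel)])
    data.frame(polygon_id = m$polygon_id[1],
               date = as.Date(days + t_abs[1], origin = "1970-01-01"),
               ndvi = stats::predict(fit,
                                     newdata = data.frame(t_rel = days)))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Green-up date by the half-amplitude method
#'
#' For one polygon-year of daily (smoothed) NDVI: the annual minimum
#' and maximum define the amplitude, and green-up is the first day on
#' the rising limb — the search is restricted to the span from the
#' annual-minimum day to the annual-maximum day — where the series
#' reaches `min + (max - min) / 2`.  The crossing is located by linear
#' interpolation between the bracketing days and rounded to the
#' nearest integer day-of-year.
#'
#' @param daily data.frame `date`, `ndvi` for a single polygon-year
#'   (a `polygon_id` column is ignored).
#' @param min_amplitude series whose annual range is below this are
#'   rejected as degenerate.
#' @return integer day-of-year of green-up.
#' @export
greenup_half_amplitude <- function(daily, min_amplitude = 1e-6) {
  assert_cols(daily, c("date", "ndvi"), "daily")
  daily <- daily[order(daily$date), ]
  v <- daily$ndvi
  if (anyNA(v)) stopf("daily series contains NA; smooth/fill first")
  i_max <- which.max(v)
  if (i_max == 1L)
    stopf("degenerate series: annual maximum on the first day; no rising limb")
  # the rising-limb minimum: the lowest point before the annual maximum
  # (a December shoulder below the spring baseline must not hijack it)
  i_min <- which.min(v[seq_len(i_max)])
  lo <- v[i_min]; hi <- v[i_max]
  if (hi - lo < min_amplitude)
    stopf("degenerate series: annual amplitude %.3g below %.3g",
          hi - lo, min_amplitude)
  half <- lo + (hi - lo) / 2
  seg <- v[i_min:i_max]
  k <- which(seg >= half)[1]            # first crossing on the rising limb
  idx <- i_min + k - 1L
  if (k == 1L) return(doy(daily$date[idx]))
  # linear interpolation between the bracketing days
  v0 <- v[idx - 1L]; v1 <- v[idx]
  frac <- (half - v0) / (v1 - v0)
  d0 <- doy(daily$date[idx - 1L])
  d1 <- doy(daily$date[idx])
  as.integer(round(d0 + frac * (d1 - d0)))
}

#' Assign occurrence records to square grid cells
#'
#' Half-open floor convention: a point at km coordinates (x, y) lands
#' in cell `(floor(x / cell), floor(y / cell))`, so boundary points
#' belong to exactly one (the higher) cell.  Rows with missing
#' coordinates are dropped and counted.
#'
#' @param records data.frame with `x_km`, `y_km` (projected km).
#' @param cell_size_km grid resolution, km.
#' @return `records` with added `cell_x`, `cell_y` and a combined
#'   `cell_id` string; attribute `n_rejected` counts dropped rows.
#' @export
grid_occurrences <- function(records, cell_size_km = 10) {
  assert_cols(records, c("x_km", "y_km"), "records")
  bad <- is.na(records$x_km) | is.na(records$y_km)
  out <- records[!bad, , drop = FALSE]
  out$cell_x <- floor(out$x_km / cell_size_km)
  out$cell_y <- floor(out$y_km / cell_size_km)
  out$cell_id <- paste0("c", out$cell_x, "_", out$cell_y)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Extract first-event dates per grid cell with inclusion filters
#'
#' Cells with fewer than `min_per_grid` sightings of a species-year are
#' discarded; if fewer than `min_grids` cells survive, the whole
#' species-year is excluded (a reported outcome, not an error).  Each
#' surviving cell contributes one event: the earliest sighting date.
#'
#' @param records gridded records with `species`, `date`, `cell_id`.
#' @param min_per_grid minimum sightings per cell.
#' @param min_grids minimum surviving cells per species-year.
#' @param event_type label attached to the events (`"FF"` insects,
#'   `"DA"` birds).
#' @return list with `events` (species, cell_id, year, event_day,
#'   event_type, n_grids) and `exclusions` (species, year, n_grids
#'   surviving when excluded).
#' @export
first_event <- function(records, min_per_grid = 3L, min_grids = 20L,
                        event_type = "FF") {
  assert_cols(records, c("species", "date", "cell_id"), "records")
  dt <- data.table::as.data.table(records)
  dt[, year := as.integer(format(date, "%Y"))]
  per_cell <- dt[, list(n_sight = .N, event_day = min(doy(date))),
                 by = c("species", "year", "cell_id")]
  per_cell <- per_cell[per_cell$n_sight >= min_per_grid]
  counts <- per_cell[, list(n_grids = .N), by = c("species", "year")]
  keep <- counts[counts$n_grids >= min_grids]
  excl <- counts[counts$n_grids < min_grids]
  events <- merge(per_cell, keep, by = c("species", "year"))
  data.table::setorderv(events, c("species", "year", "cell_id"))
  events <- as.data.frame(events[, list(species, year, cell_id,
                                        event_day, n_grids)])
  events$event_type <- rep(event_type, length.out = nrow(events))
  list(events = events,
       exclusions = as.data.frame(excl))
}

#' National summary of event dates per species-year
#'
#' Median (midpoint convention for even counts), quartiles and range of
#' the per-grid event days; the median is what the interaction indices
#' consume as the national event date.
#'
#' @param events event data.frame from [first_event()] (or green-up
#'   events with the same columns).
#' @return data.frame with one row per species-year.
#' @export
summarize_events <- function(events) {
  assert_cols(events, c("species", "year", "event_day"), "events")
  if (nrow(events) == 0L) stopf("no events to summarise")
  dt <- data.table::as.data.table(events)
  out <- dt[, list(n = .N,
                   median = stats::median(event_day),
                   q25 = unname(stats::quantile(event_day, 0.25, type = 7)),
                   q75 = unname(stats::quantile(event_day, 0.75, type = 7)),
                   min = min(event_day), max = max(event_day)),
            by = c("species", "year")]
  data.table::setorderv(out, c("species", "year"))
  as.data.frame(out)
}

#' Green-up events for every polygon-year of an NDVI table
#'
#' Convenience pipeline: monthly-max compositing, climatology fill,
#' LOESS smoothing/interpolation, then half-amplitude extraction per
#' polygon and calendar year.
#'
#' @param series raw NDVI data.frame (`polygon_id`, `date`, `ndvi`).
#' @param span LOESS span passed to [smooth_and_interpolate()].
#' @return data.frame `species` (= polygon_id), `year`, `cell_id`,
#'   `event_day`, `event_type = "GU"`.
#' @export
extract_greenup <- function(series, span = 0.25) {
  monthly <- monthly_max_composite(series)
  filled <- fill_climatology(monthly)
  daily <- smooth_and_interpolate(filled, span = span)
  daily$year <- as.integer(format(daily$date, "%Y"))
  parts <- lapply(split(daily, list(daily$polygon_id, daily$year),
                        drop = TRUE), function(d) {
    # need both limbs inside the year to define an annual amplitude
    if (nrow(d) < 200L) return(NULL)
    gu <- tryCatch(greenup_half_amplitude(d), error = function(e) NA_integer_)
    if (is.na(gu)) return(NULL)
    data.frame(species = d$polygon_id[1], year = d$year[1],
               cell_id = d$polygon_id[1], event_day = gu,
               event_type = "GU")
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
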