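# Relative sliding time-window regression: enumerate every candidate
# window 0..max_lag days before each record's own event date, fit an
# OLS of event day on the aggregated weather, select by AICc, and
# attach a randomisation significance (Pc).

#' Candidate window specification
#'
#' A window runs from `open` days before the event (further in the
#' past) to `close` days before the event (nearer it), inclusive at
#' both ends; day 0 is the event day itself.
#'
#' @param open,close non-negative integers, `0 <= close <= open <= 180`.
#' @param variable weather variable, one of `"TMIN"`, `"TMAX"`,
#'   `"TPPT"`.
#' @param statistic aggregate statistic over the window; default mean
#'   for temperatures, sum for precipitation.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(open, close, variable = c("TMIN", "TMAX", "TPPT"),
                        statistic = NULL) {
  variable <- match.arg(variable)
  if (close < 0 || open < close)
    stopf("invalid window: need 0 <= close <= open")
  statistic <- statistic %||% default_statistic(variable)
  if (!statistic %in% c("mean", "sum"))
    stopf("statistic must be 'mean' or 'sum'")
  structure(list(open = as.integer(open), close = as.integer(close),
                 variable = variable, statistic = statistic),
            class = "window_spec")
}

variable_column <- function(variable) {
  c(TMIN = "tmin", TMAX = "tmax", TPPT = "tppt")[[variable]]
}

#' Enumerate all candidate windows on a lag lattice
#'
#' All `(open, close)` pairs with `open >= close` on the `step`
#' lattice from 0 to `max_lag` days before the event, ordered by open
#' then close ascending.  With `T = max_lag/step + 1` lags this yields
#' `T(T+1)/2` windows (16,471 for the default 0-180 range).
#'
#' @param max_lag furthest lag considered, days before the event.
#' @param step lattice step, days.
#' @return data.frame with integer columns `open`, `close`.
#' @export
enumerate_windows <- function(max_lag = 180L, step = 1L) {
  if (max_lag < 0 || step < 1) stopf("need max_lag >= 0 and step >= 1")
  lags <- seq.int(0L, as.integer(max_lag), by = as.integer(step))
  out <- do.call(rbind, lapply(lags, function(o)
    data.frame(open = o, close = lags[lags <= o])))
  rownames(out) <- NULL
  out
}

# Per-cell date-indexed lookup used to build lag matrices quickly (the
# permutation test rebuilds the matrix for every shuffle).
weather_index <- function(weather, variable) {
  col <- variable_column(variable)
  assert_cols(weather, c("cell_id", "date", col), "weather")
  sp <- split(seq_len(nrow(weather)), weather$cell_id)
  idx <- lapply(sp, function(i) {
    d <- weather$date[i]; v <- weather[[col]][i]
    o <- order(d)
    d <- d[o]; v <- v[o]
    start <- d[1]
    vec <- rep(NA_real_, as.integer(d[length(d)] - start) + 1L)
    vec[as.integer(d - start) + 1L] <- v
    list(start = start, values = vec)
  })
  structure(list(cells = idx, variable = variable),
            class = "weather_index")
}

# Lag matrix: row per event, column j holds the weather value
# (event_date - (j-1)) in the event's own cell.  Errors name the first
# uncovered (event, date) pair.
lag_matrix <- function(widx, cell_ids, event_dates, max_lag) {
  n <- length(cell_ids)
  L <- matrix(NA_real_, n, max_lag + 1L)
  for (i in seq_len(n)) {
    ci <- widx$cells[[as.character(cell_ids[i])]]
    if (is.null(ci))
      stopf("coverage error: no weather for cell %s", cell_ids[i])
    pos <- as.integer(event_dates[i] - ci$start) + 1L
    want <- pos - 0:max_lag
    if (want[length(want)] < 1L || pos > length(ci$values))
      stopf("coverage error: cell %s event on %s needs weather back to %s",
            cell_ids[i], format(event_dates[i]),
            format(event_dates[i] - max_lag))
    L[i, ] <- ci$values[want]
    if (anyNA(L[i, ])) {
      miss <- which(is.na(L[i, ]))[1] - 1L
      stopf("coverage error: cell %s missing weather on %s (lag %d of event %s)",
            cell_ids[i], format(event_dates[i] - miss), miss,
            format(event_dates[i]))
    }
  }
  L
}

events_dates <- function(events) {
  assert_cols(events, c("cell_id", "year", "event_day"), "events")
  date_from_doy(events$year, events$event_day)
}

#' Aggregate weather over a relative window, one scalar per event
#'
#' For each event the covariate is `statistic` of the weather values on
#' days `event_date - open` through `event_date - close` inclusive in
#' the event's own grid cell, reaching into the previous calendar year
#' when the window crosses 1 January.  Windows are relative: two events
#' on different days or cells aggregate different calendar spans.
#'
#' @param weather daily weather data.frame.
#' @param events events data.frame (`cell_id`, `year`, `event_day`).
#' @param spec a [window_spec()].
#' @return numeric vector, one covariate per event row.
#' @export
aggregate_relative <- function(weather, events, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (inherits(weather, "weather_index") &&
      weather$variable != spec$variable)
    stopf("weather index was built for %s, spec wants %s",
          weather$variable, spec$variable)
  widx <- if (inherits(weather, "weather_index")) weather
          else weather_index(weather, spec$variable)
  L <- lag_matrix(widx, events$cell_id, events_dates(events), spec$open)
  cols <- (spec$close:spec$open) + 1L
  s <- rowSums(L[, cols, drop = FALSE])
  if (spec$statistic == "mean") s / length(cols) else s
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)` for a model with `k`
#' estimated parameters (Gaussian likelihood with the variance MLE
#' counts as one of them) on `n` observations.
#'
#' @param log_likelihood maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size, must exceed `k + 1`.
#' @return numeric AICc.
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n <= k + 1) stopf("sample-size error: AICc needs n > k + 1 (n=%d, k=%d)",
                        n, k)
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

gauss_loglik <- function(rss, n) {
  sigma2 <- rss / n                     # variance MLE
  if (sigma2 <= 0) return(Inf)          # perfect fit: likelihood unbounded
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

#' Fit the linear model for one candidate window
#'
#' OLS of event day on the window covariate (intercept + slope +
#' variance, k = 3) against the intercept-only null (k = 2);
#' `delta_aicc = AICc(fit) - AICc(null)`.  A zero-variance covariate is
#' a degenerate window: slope is undefined and `delta_aicc` is `+Inf`
#' so it can never be selected.
#'
#' @param events events data.frame (needs >= 4 rows).
#' @param weather daily weather data.frame or prebuilt index.
#' @param spec a [window_spec()].
#' @return an object of class `window_fit`: spec, slope, intercept,
#'   aicc, null_aicc, delta_aicc, r2, n.
#' @export
fit_window <- function(events, weather, spec) {
  n <- nrow(events)
  if (n < 4L) stopf("sample-size error: need >= 4 events, got %d", n)
  x <- aggregate_relative(weather, events, spec)
  y <- events$event_day
  ols_window_fit(x, y, spec)
}

ols_window_fit <- function(x, y, spec) {
  n <- length(y)
  sy <- sum(y); syy <- sum(y^2) - sy^2 / n
  sx <- sum(x); sxx <- sum(x^2) - sx^2 / n
  sxy <- sum(x * y) - sx * sy / n
  null_aicc <- aicc(gauss_loglik(syy, n), 2L, n)
  if (sxx <= .Machine$double.eps * max(1, sum(x^2))) {
    return(structure(list(spec = spec, slope = NA_real_,
                          intercept = NA_real_, aicc = Inf,
                          null_aicc = null_aicc, delta_aicc = Inf,
                          r2 = NA_real_, n = n),
                     class = "window_fit"))
  }
  slope <- sxy / sxx
  intercept <- (sy - slope * sx) / n
  rss <- max(0, syy - sxy^2 / sxx)
  fit_aicc <- aicc(gauss_loglik(rss, n), 3L, n)
  structure(list(spec = spec, slope = slope, intercept = intercept,
                 aicc = fit_aicc, null_aicc = null_aicc,
                 delta_aicc = fit_aicc - null_aicc,
                 r2 = if (syy > 0) 1 - rss / syy else NA_real_, n = n),
            class = "window_fit")
}

#' @export
print.window_fit <- function(x, ...) {
  cat(sprintf(
    "window_fit: %s %s window open %d close %d | slope %.4g dAICc %.3f n %d\n",
    x$spec$variable, x$spec$statistic, x$spec$open, x$spec$close,
    x$slope, x$delta_aicc, x$n))
  invisible(x)
}

# Vectorised search over every enumerated window.  Returns the full
# trace (open, close, slope, aicc, delta_aicc) plus the selected row.
window_search <- function(y, L, wins, statistic, n) {
  Cz <- cbind(0, t(apply(L, 1L, cumsum)))   # n x (max_lag + 2)
  X <- Cz[, wins$open + 2L, drop = FALSE] -
    Cz[, wins$close + 1L, drop = FALSE]
  len <- wins$open - wins$close + 1L
  if (statistic == "mean") X <- sweep(X, 2L, len, "/")
  sy <- sum(y); syy <- sum(y^2) - sy^2 / n
  sx <- colSums(X)
  sxx <- colSums(X^2) - sx^2 / n
  sxy <- colSums(X * y) - sx * sy / n
  ok <- sxx > .Machine$double.eps * pmax(1, colSums(X^2))
  slope <- ifelse(ok, sxy / sxx, NA_real_)
  rss <- pmax(0, syy - ifelse(ok, sxy^2 / sxx, 0))
  sigma2 <- rss / n
  logl <- ifelse(sigma2 > 0, -n / 2 * (log(2 * pi * sigma2) + 1), Inf)
  k <- 3L
  a <- ifelse(ok, -2 * logl + 2 * k + 2 * k * (k + 1) / (n - k - 1), Inf)
  null_aicc <- aicc(gauss_loglik(syy, n), 2L, n)
  list(trace = data.frame(open = wins$open, close = wins$close,
                          slope = slope, aicc = a,
                          delta_aicc = a - null_aicc),
       null_aicc = null_aicc,
       sx = sx, intercept_of = function(j)
         (sy - (sxy[j] / sxx[j]) * sx[j]) / n)
}

select_best <- function(trace) {
  # ties: shorter window first, then smaller close
  ord <- order(trace$aicc, trace$open - trace$close, trace$close)
  ord[1]
}

#' Best relative window by exhaustive AICc search
#'
#' Enumerates every window on the lag lattice, fits the per-window OLS,
#' and returns the fit minimising AICc.  Ties are broken towards the
#' shorter window, then the smaller close.
#'
#' @inheritParams fit_window
#' @param variable weather variable.
#' @param statistic aggregate statistic (default per variable).
#' @param max_lag,step search range and lattice step, days.
#' @param return_trace keep the full search trace in the result
#'   (`$trace`)?
#' @return a `window_fit` with added `species`/`year` when the events
#'   carry a single value of each.
#' @export
best_window <- function(events, weather, variable = "TMIN",
                        statistic = NULL, max_lag = 180L, step = 1L,
                        return_trace = FALSE) {
  n <- nrow(events)
  if (n < 4L) stopf("sample-size error: need >= 4 events, got %d", n)
  statistic <- statistic %||% default_statistic(variable)
  widx <- if (inherits(weather, "weather_index")) weather
          else weather_index(weather, variable)
  wins <- enumerate_windows(max_lag, step)
  L <- lag_matrix(widx, events$cell_id, events_dates(events), max_lag)
  sr <- window_search(events$event_day, L, wins, statistic, n)
  j <- select_best(sr$trace)
  spec <- window_spec(sr$trace$open[j], sr$trace$close[j], variable,
                      statistic)
  fit <- ols_window_fit(aggregate_relative(widx, events, spec),
                        events$event_day, spec)
  if (length(unique(events$species %||% NA)) == 1L)
    fit$species <- events$species[1]
  if (length(unique(events$year)) == 1L) fit$year <- events$year[1]
  if (return_trace) fit$trace <- sr$trace
  fit
}

#' Randomisation significance (Pc) of the selected window
#'
#' Permutes event days across records `n_rand` times, reruns the whole
#' window search per permutation (the covariates change too, because
#' windows are relative to each record's event date), and reports
#' `pc = (1 + #{permuted dAICc <= observed dAICc}) / (1 + n_rand)`: the
#' probability that a search on signal-free data finds an improvement
#' at least as large as the observed one.
#'
#' @inheritParams best_window
#' @param n_rand number of permutations (>= 5).
#' @param seed integer seed for the permutations.
#' @return list with `pc`, `observed` (`window_fit`) and
#'   `perm_delta_aicc`.
#' @export
randomization_pc <- function(events, weather, variable = "TMIN",
                             statistic = NULL, n_rand = 100L, seed = 1L,
                             max_lag = 180L, step = 1L) {
  if (n_rand < 5L) stopf("n_rand must be >= 5")
  statistic <- statistic %||% default_statistic(variable)
  widx <- if (inherits(weather, "weather_index")) weather
          else weather_index(weather, variable)
  obs <- best_window(events, widx, variable, statistic, max_lag, step)
  wins <- enumerate_windows(max_lag, step)
  n <- nrow(events)
  perm_delta <- with_seed(seed, vapply(seq_len(n_rand), function(r) {
    ev <- events
    ev$event_day <- sample(ev$event_day)
    L <- lag_matrix(widx, ev$cell_id, events_dates(ev), max_lag)
    sr <- window_search(ev$event_day, L, wins, statistic, n)
    min(sr$trace$delta_aicc)
  }, numeric(1)))
  pc <- (1 + sum(perm_delta <= obs$delta_aicc)) / (1 + n_rand)
  list(pc = pc, observed = obs, perm_delta_aicc = perm_delta)
}

#' Window scan across species-years and weather variables
#'
#' Runs [best_window()] (and optionally [randomization_pc()]) for every
#' (species, year) group in `events` and every requested variable,
#' returning one tidy row per combination: the layout of a per-species
#' critical-window table (N, national median event day, window open and
#' close, slope, dAICc, Pc).
#'
#' @param events event data.frame (`species`, `year`, `cell_id`,
#'   `event_day`).
#' @param weather daily weather data.frame.
#' @param variables weather variables to scan.
#' @param max_lag,step search range, days.
#' @param n_rand permutations for Pc; `0` skips the Pc column.
#' @param seed base seed for the permutation streams.
#' @return data.frame with one row per species x year x variable.
#' @export
scan_windows <- function(events, weather,
                         variables = c("TMIN", "TMAX", "TPPT"),
                         max_lag = 180L, step = 1L, n_rand = 0L,
                         seed = 1L) {
  assert_cols(events, c("species", "year", "cell_id", "event_day"),
              "events")
  groups <- split(events, list(events$species, events$year), drop = TRUE)
  rows <- list()
  for (g in groups) {
    for (v in variables) {
      widx <- weather_index(weather, v)
      bw <- best_window(g, widx, v, max_lag = max_lag, step = step)
      pc <- NA_real_
      if (n_rand > 0L) {
        sseed <- derive_seed(seed, length(rows) + 1L)
        pc <- randomization_pc(g, widx, v, n_rand = n_rand,
                               seed = sseed, max_lag = max_lag,
                               step = step)$pc
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species = g$species[1], year = g$year[1], n = nrow(g),
        event_median = stats::median(g$event_day), variable = v,
        statistic = bw$spec$statistic, window_open = bw$spec$open,
        window_close = bw$spec$close, slope = bw$slope,
        delta_aicc = bw$delta_aicc, pc = pc)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
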