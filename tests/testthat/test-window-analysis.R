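test_that("window enumeration covers the triangular lattice", {
  w <- enumerate_windows(2, 1)
  expect_equal(w, data.frame(open = c(0L, 1L, 1L, 2L, 2L, 2L),
                             close = c(0L, 0L, 1L, 0L, 1L, 2L)))
  expect_equal(nrow(enumerate_windows(180, 1)), 16471L)  # 181*182/2
  expect_equal(nrow(enumerate_windows(0)), 1L)
  expect_equal(nrow(enumerate_windows(20, 5)), 15L)      # T=5 lags
})

test_that("relative aggregation matches a brute-force day loop", {
  cfg <- weather_sim_config(6, "2014-06-01", "2015-07-31", seed = 12)
  w <- gen_weather(cfg, "daily")$data
  ev <- data.frame(species = "X", year = 2015, cell_id = 1:6,
                   event_day = c(95, 110, 120, 131, 144, 150))
  # (0,0) mean = the value on the event day itself
  x0 <- aggregate_relative(w, ev, window_spec(0, 0, "TMIN"))
  key <- paste(w$cell_id, w$date)
  ed <- as.Date("2015-01-01") + ev$event_day - 1
  expect_equal(x0, w$tmin[match(paste(ev$cell_id, ed), key)])
  # constant weather: mean = c, sum = c * length
  wc <- make_constant_weather(1:6, seq(as.Date("2014-06-01"),
                                       as.Date("2015-07-31"), by = "day"),
                              tmin = 4)
  expect_equal(aggregate_relative(wc, ev, window_spec(50, 25, "TMIN")),
               rep(4, 6))
  expect_equal(
    aggregate_relative(wc, ev, window_spec(50, 25, "TMIN",
                                           statistic = "sum")),
    rep(4 * 26, 6))
  # random series vs explicit 26-day loop
  x <- aggregate_relative(w, ev, window_spec(50, 25, "TPPT"))
  want <- vapply(seq_len(6), function(i) {
    days <- seq(ed[i] - 50, ed[i] - 25, by = "day")
    sum(w$tppt[match(paste(ev$cell_id[i], days), key)])
  }, numeric(1))
  expect_equal(x, want)
  # uncovered day is a coverage error naming the date
  expect_error(
    aggregate_relative(w[w$date >= as.Date("2015-01-01"), ], ev,
                       window_spec(120, 100, "TMIN")),
    "coverage")
})

test_that("AICc follows the corrected formula", {
  expect_equal(aicc(-50, 2, 100), 104 + 12 / 97)
  # penalty monotonicity at equal likelihood
  expect_lt(aicc(-10, 2, 20), aicc(-10, 3, 20))
  # AICc converges to AIC for large n
  aic <- -2 * (-10) + 2 * 3
  expect_lt(aicc(-10, 3, 1e6) - aic, 1e-4)
  expect_error(aicc(-10, 3, 4), "sample-size")
})

test_that("fit_window: perfect fits, degenerate covariates, recovery", {
  # weather constant in time but varying across cells: the covariate
  # equals the cell constant for any window, so events can be made
  # exactly linear in it without moving the relative windows
  dates <- seq(as.Date("2014-06-01"), as.Date("2015-07-31"), "day")
  consts <- seq(2, 11, length.out = 10)
  w <- do.call(rbind, lapply(1:10, function(c)
    data.frame(cell_id = c, date = dates, tmax = consts[c] + 6,
               tmin = consts[c], tppt = 0)))
  spec <- window_spec(30, 10, "TMIN")
  ev <- data.frame(species = "X", year = 2015, cell_id = 1:10,
                   event_day = 100 + 3 * consts)
  f <- fit_window(ev, w, spec)
  expect_equal(f$slope, 3, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_lt(f$delta_aicc, -20)
  # constant covariate -> sentinel that can never be selected
  wc <- make_constant_weather(1:10, dates)
  fdeg <- fit_window(ev, wc, spec)
  expect_true(is.na(fdeg$slope))
  expect_equal(fdeg$delta_aicc, Inf)
  expect_error(fit_window(ev[1:3, ], w, spec), "sample-size")
  # slope recovery: planted slope -2, residual sd 1, 20 seeds
  slopes <- vapply(1:20, function(s) {
    world <- make_planted_world(s)
    spec50 <- window_spec(50, 25, "TMIN")
    fit_window(world$events, world$weather$data, spec50)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-2)),
            2.576 * sd(slopes) / sqrt(20))
})

test_that("best_window agrees with the brute-force triple loop", {
  set.seed(77)
  cfg <- weather_sim_config(12, "2014-06-01", "2015-06-30", seed = 5)
  w <- gen_weather(cfg, "daily")$data
  for (v in c("TMIN", "TPPT")) {
    ev <- data.frame(species = "X", year = 2015, cell_id = 1:12,
                     event_day = sample(100:140, 12))
    st <- if (v == "TPPT") "sum" else "mean"
    got <- best_window(ev, w, v, max_lag = 8)
    want <- bf_best_window(ev, w, v, st, 8)
    expect_equal(got$spec$open, want$open)
    expect_equal(got$spec$close, want$close)
    expect_equal(got$aicc, want$aicc, tolerance = 1e-9)
    expect_equal(got$slope, want$slope, tolerance = 1e-9)
  }
})

test_that("enlarging the search never worsens the optimum", {
  set.seed(3)
  cfg <- weather_sim_config(10, "2014-06-01", "2015-06-30", seed = 19)
  w <- gen_weather(cfg, "daily")$data
  ev <- data.frame(species = "X", year = 2015, cell_id = 1:10,
                   event_day = sample(110:150, 10))
  a_small <- best_window(ev, w, "TMIN", max_lag = 10)$aicc
  a_big <- best_window(ev, w, "TMIN", max_lag = 25)$aicc
  expect_lte(a_big, a_small)
  # selected dAICc is minimal over the stored search trace
  tr <- best_window(ev, w, "TMIN", max_lag = 25, return_trace = TRUE)
  expect_equal(min(tr$trace$delta_aicc), tr$delta_aicc,
               tolerance = 1e-9)
})

test_that("randomisation pc: rank formula and cell-relabelling invariance", {
  world <- make_planted_world(1)
  res <- randomization_pc(world$events, world$weather$data, "TMIN",
                          n_rand = 19, seed = 44)
  expect_equal(length(res$perm_delta_aicc), 19L)
  # strong planted signal: observed beats every permutation -> 1/20
  expect_true(all(res$perm_delta_aicc > res$observed$delta_aicc))
  expect_equal(res$pc, 1 / 20)
  # relabelling grid cells consistently leaves pc unchanged
  relabel <- function(x) paste0("z", x)
  ev2 <- world$events; ev2$cell_id <- relabel(ev2$cell_id)
  w2 <- world$weather$data; w2$cell_id <- relabel(w2$cell_id)
  res2 <- randomization_pc(ev2, w2, "TMIN", n_rand = 19, seed = 44)
  expect_equal(res2$pc, res$pc)
  expect_equal(res2$observed$spec$open, res$observed$spec$open)
  expect_error(randomization_pc(world$events, world$weather$data,
                                "TMIN", n_rand = 3), "n_rand")
})

test_that("window recovery bias shrinks as residual noise shrinks", {
  mid_bias <- vapply(c(4, 1, 0.1), function(sdres) {
    mids <- vapply(1:5, function(s) {
      world <- make_planted_world(s + 100, residual_sd = sdres)
      bw <- best_window(world$events, world$weather$data, "TMIN",
                        max_lag = 90)
      (bw$spec$open + bw$spec$close) / 2
    }, numeric(1))
    abs(mean(mids) - 37.5)
  }, numeric(1))
  expect_lte(mid_bias[3], mid_bias[1] + 1)
  expect_lt(mid_bias[3], 5)
})

test_that("scan_windows returns one tidy row per species-year-variable", {
  world <- make_planted_world(7, n_grids = 20)
  sc <- scan_windows(world$events, world$weather$data,
                     variables = c("TMIN", "TMAX"), max_lag = 40,
                     n_rand = 0)
  expect_equal(nrow(sc), 2L)
  expect_setequal(sc$variable, c("TMIN", "TMAX"))
  expect_equal(sc$n, c(20L, 20L))
  expect_true(all(sc$window_open >= sc$window_close))
})
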