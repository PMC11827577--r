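# Run configuration, stage orchestration, input validation and
# manifest writing.  All artefacts are UTF-8 CSV with ISO-8601 dates
# and deterministic row order, so identical config + seed reproduces
# identical bytes.

#' Pipeline run configuration
#'
#' Every analysis parameter with its conventional default: 10 km
#' grid, >= 3 sightings per grid, >= 20 grids per species-year,
#' relative windows 0-180 days at 1-day step, mean aggregation for
#' temperatures and sum for precipitation, ICAO 6.49 K/km lapse rate.
#' `sim` controls the synthetic-data stage (cells, year, planted
#' windows per simulated species, planted green-up).
#'
#' @param cell_size_km,min_per_grid,min_grids occurrence gridding and
#'   inclusion filters.
#' @param max_lag,step window search range, days.
#' @param statistics named character vector: aggregate statistic per
#'   weather variable.
#' @param n_rand permutations for Pc (0 disables).
#' @param loess_span NDVI smoothing span.
#' @param lapse_rate temperature correction, K/km.
#' @param pool AL' standardisation pool mode.
#' @param seed run seed; per-stage substreams are derived from it.
#' @param out output directory for artefacts.
#' @param sim list of synthetic-stage settings (see Details).
#' @return object of class `run_config`.
#' @export
run_config <- function(cell_size_km = 10, min_per_grid = 3L,
                       min_grids = 20L, max_lag = 180L, step = 1L,
                       statistics = c(TMIN = "mean", TMAX = "mean",
                                      TPPT = "sum"),
                       n_rand = 100L, loess_span = 0.25,
                       lapse_rate = 6.49,
                       pool = c("pair_class", "species_pair"),
                       seed = 1L, out = "phenosync_run",
                       sim = NULL) {
  pool <- match.arg(pool)
  stopifnot(cell_size_km > 0, min_per_grid >= 1, min_grids >= 1,
            max_lag >= 0, step >= 1, n_rand >= 0, loess_span > 0,
            all(statistics %in% c("mean", "sum")))
  cfg <- list(cell_size_km = cell_size_km,
              min_per_grid = as.integer(min_per_grid),
              min_grids = as.integer(min_grids),
              max_lag = as.integer(max_lag), step = as.integer(step),
              statistics = statistics, n_rand = as.integer(n_rand),
              loess_span = loess_span, lapse_rate = lapse_rate,
              pool = pool, seed = as.integer(seed), out = out,
              sim = sim %||% default_sim_config())
  structure(cfg, class = "run_config")
}

# Synthetic-world defaults for the pipeline's simulate stage: a small
# roster of 2 birds and 2 insects with planted TMIN windows plus one
# vegetation polygon with a planted green-up, over one analysis year.
default_sim_config <- function() {
  list(n_cells = 30L, year = 2015L, n_grids = 25L,
       sightings_per_grid = 4L,
       greenup_day = 64L, ndvi_years = 3L,
       species = list(
         I1 = list(group = "insect", window = list(
           variable = "TMIN", open = 50L, close = 25L, slope = -2,
           intercept = 100, residual_sd = 1)),
         I2 = list(group = "insect", window = list(
           variable = "TMIN", open = 40L, close = 15L, slope = -1.5,
           intercept = 112, residual_sd = 1)),
         B1 = list(group = "bird", window = list(
           variable = "TMAX", open = 45L, close = 20L, slope = -1.2,
           intercept = 118, residual_sd = 1)),
         B2 = list(group = "bird", window = list(
           variable = "TMIN", open = 35L, close = 10L, slope = -1,
           intercept = 126, residual_sd = 1))))
}

#' Serialise / restore a run configuration
#'
#' Configs round-trip losslessly through JSON.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `read_config` returns the restored `run_config`.
#' @export
write_config <- function(config, path) {
  raw <- unclass(config)
  raw$statistics <- as.list(raw$statistics)  # keep names in JSON
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$statistics <- unlist(raw$statistics)
  cfg <- run_config(cell_size_km = raw$cell_size_km,
                    min_per_grid = raw$min_per_grid,
                    min_grids = raw$min_grids, max_lag = raw$max_lag,
                    step = raw$step, statistics = raw$statistics,
                    n_rand = raw$n_rand, loess_span = raw$loess_span,
                    lapse_rate = raw$lapse_rate, pool = raw$pool,
                    seed = raw$seed, out = raw$out)
  cfg$sim <- raw$sim
  cfg
}

artefact_path <- function(config, name) file.path(config$out, name)

write_artefact <- function(df, config, name) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  path <- artefact_path(config, name)
  df <- as.data.frame(df)
  for (col in names(df))
    if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  path
}

read_artefact <- function(config, name, required_by = NULL) {
  path <- artefact_path(config, name)
  if (!file.exists(path))
    stopf("dependency error: stage '%s' needs missing artefact %s",
          required_by %||% "?", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(df)) df$date <- as.Date(df$date)
  df
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in their canonical order —
#' `simulate`, `prep-weather`, `extract-greenup`, `extract-events`,
#' `windows`, `indices`, `network` — each reading its inputs from and
#' writing its outputs to `config$out`, then writes `manifest.json`
#' (effective config, seed, versions, per-artefact row counts and MD5
#' checksums).  Identical config + seed reproduces identical artefact
#' bytes.
#'
#' @param config a [run_config()].
#' @param stages ordered subset of stage names; default all.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "prep-weather",
                                    "extract-greenup", "extract-events",
                                    "windows", "indices", "network")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("simulate", "prep-weather", "extract-greenup",
                  "extract-events", "windows", "indices", "network")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  for (s in stages) {
    switch(s,
           "simulate" = stage_simulate(config),
           "prep-weather" = stage_prep_weather(config),
           "extract-greenup" = stage_extract_greenup(config),
           "extract-events" = stage_extract_events(config),
           "windows" = stage_windows(config),
           "indices" = stage_indices(config),
           "network" = stage_network(config))
  }
  write_manifest(config, stages)
}

stage_simulate <- function(config) {
  sim <- config$sim
  year <- as.integer(sim$year)
  wcfg <- weather_sim_config(
    n_cells = sim$n_cells,
    date_start = as.Date(sprintf("%d-01-01", year - 1L)),
    date_end = as.Date(sprintf("%d-12-31", year)),
    cell_size_km = config$cell_size_km,
    seed = derive_seed(config$seed, 1L))
  w <- gen_weather(wcfg, "daily")
  dem <- gen_dem(w$cells, seed = derive_seed(config$seed, 2L))
  write_artefact(w$data, config, "weather_raw.csv")
  write_artefact(w$cells[, c("cell_id", "x_km", "y_km", "model_elev")],
                 config, "cells.csv")
  write_artefact(dem$data, config, "dem_points.csv")

  ndvi <- do.call(rbind, lapply(seq_len(sim$ndvi_years), function(i)
    gen_ndvi(green_up_day = sim$greenup_day,
             year = year - sim$ndvi_years + i,
             seed = derive_seed(config$seed, 10L + i),
             polygon_id = "V1")$data))
  write_artefact(ndvi, config, "ndvi.csv")

  occ <- list(); truths <- list()
  for (k in seq_along(sim$species)) {
    sp <- names(sim$species)[k]
    info <- sim$species[[k]]
    pw <- planted_window(info$window$variable, info$window$open,
                         info$window$close, info$window$slope,
                         info$window$intercept, info$window$residual_sd)
    g <- gen_occurrences(w, pw, n_grids = sim$n_grids,
                         sightings_per_grid = sim$sightings_per_grid,
                         year = year,
                         seed = derive_seed(config$seed, 100L + k),
                         species = sp,
                         cell_size_km = config$cell_size_km)
    occ[[k]] <- cbind(g$data, group = info$group)
    truths[[k]] <- data.frame(species = sp, variable = pw$variable,
                              open = pw$open_days, close = pw$close_days,
                              slope = pw$slope, intercept = pw$intercept)
  }
  write_artefact(do.call(rbind, occ), config, "occurrences.csv")
  write_artefact(do.call(rbind, truths), config, "planted_windows.csv")
  invisible(config)
}

stage_prep_weather <- function(config) {
  raw <- read_artefact(config, "weather_raw.csv", "prep-weather")
  cells <- read_artefact(config, "cells.csv", "prep-weather")
  dem <- read_artefact(config, "dem_points.csv", "prep-weather")
  cells <- regrid_dem_nearest(dem, cells)
  daily <- correct_temperature(raw, lapse_rate = config$lapse_rate,
                               elev = cells[, c("cell_id", "model_elev",
                                                "dem_elev")])
  daily <- daily[order(daily$cell_id, daily$date), ]
  write_artefact(daily, config, "weather_daily.csv")
  invisible(config)
}

stage_extract_greenup <- function(config) {
  ndvi <- read_artefact(config, "ndvi.csv", "extract-greenup")
  gu <- extract_greenup(ndvi, span = config$loess_span)
  write_artefact(gu, config, "greenup_events.csv")
  invisible(config)
}

stage_extract_events <- function(config) {
  occ <- read_artefact(config, "occurrences.csv", "extract-events")
  gridded <- grid_occurrences(occ, config$cell_size_km)
  res <- first_event(gridded, config$min_per_grid, config$min_grids,
                     event_type = "FF")
  # translate grid-cell labels back to the weather table's cell ids so
  # the window stage can look weather up per event
  cells <- read_artefact(config, "cells.csv", "extract-events")
  label <- paste0("c", floor(cells$x_km / config$cell_size_km), "_",
                  floor(cells$y_km / config$cell_size_km))
  hit <- match(res$events$cell_id, label)
  res$events$cell_id <- ifelse(is.na(hit), res$events$cell_id,
                               cells$cell_id[hit])
  # bird records get the DA label; the filter logic is identical
  if ("group" %in% names(occ)) {
    res$events$event_type <-
      ifelse(res$events$species %in%
               unique(occ$species[occ$group == "bird"]), "DA", "FF")
  }
  write_artefact(res$events, config, "events.csv")
  write_artefact(res$exclusions, config, "exclusions.csv")
  if (nrow(res$exclusions))
    message(sprintf("excluded %d species-year(s): %s",
                    nrow(res$exclusions),
                    paste(res$exclusions$species, res$exclusions$year,
                          collapse = "; ")))
  invisible(config)
}

stage_windows <- function(config) {
  events <- read_artefact(config, "events.csv", "windows")
  weather <- read_artefact(config, "weather_daily.csv", "windows")
  scan <- scan_windows(events, weather,
                       variables = names(config$statistics),
                       max_lag = config$max_lag, step = config$step,
                       n_rand = config$n_rand,
                       seed = derive_seed(config$seed, 3L))
  write_artefact(scan, config, "windows.csv")
  invisible(config)
}

stage_indices <- function(config) {
  events <- read_artefact(config, "events.csv", "indices")
  gu <- tryCatch(read_artefact(config, "greenup_events.csv", "indices"),
                 error = function(e) NULL)
  groups <- unique(events[, c("species", "event_type")])
  roster <- data.frame(
    code = groups$species,
    common_name = groups$species,
    group = ifelse(groups$event_type == "DA", "bird", "insect"),
    trophic_level = ifelse(groups$event_type == "DA", 3L, 2L))
  sums <- summarize_events(events)
  if (!is.null(gu) && nrow(gu)) {
    roster <- rbind(roster,
                    data.frame(code = unique(gu$species),
                               common_name = unique(gu$species),
                               group = "vegetation", trophic_level = 1L))
    sums <- rbind(sums, summarize_events(gu)[, names(sums)])
  }
  # only years every trophic level observed contribute to the indices
  scores <- al_scores(sums, roster, pool = config$pool)
  write_artefact(scores, config, "al_scores.csv")

  win <- read_artefact(config, "windows.csv", "indices")
  iic <- iicwm_from_runs(scores, win, roster)
  write_artefact(iic, config, "iicwm.csv")
  if (!is.null(gu) && nrow(gu)) {
    q <- qai_from_scores(scores, roster)
    write_artefact(q, config, "qai.csv")
  }
  invisible(config)
}

# Per-year IICWM for every bird-insect pair with complete windows.
iicwm_from_runs <- function(scores, windows, roster) {
  bi <- scores[scores$pair_class == "3-2", ]
  rows <- list()
  for (i in seq_len(nrow(bi))) {
    yr <- bi$year[i]
    wo_of <- function(sp) {
      w <- windows[windows$species == sp & windows$year == yr, ]
      stats::setNames(w$window_open[match(c("TMIN", "TMAX", "TPPT"),
                                          w$variable)],
                      c("TMIN", "TMAX", "TPPT"))
    }
    wo <- tryCatch(wo_composite(wo_of(bi$species_hi[i]),
                                wo_of(bi$species_lo[i])),
                   error = function(e) NA_real_)
    if (is.na(wo) || wo == 0) next
    ic <- iicwm(bi$al[i], as.numeric(wo))
    rows[[length(rows) + 1L]] <- data.frame(
      bird = bi$species_hi[i], insect = bi$species_lo[i], year = yr,
      al = bi$al[i], wo = as.numeric(wo), iicwm = ic$value,
      category = ic$category)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(bird = character(), insect = character(),
               year = integer(), al = numeric(), wo = numeric(),
               iicwm = numeric(), category = character())
  out[order(out$bird, out$insect, out$year), , drop = FALSE]
}

# QAI per bird-insect pair using median AL' over years for the upper
# pair and the insect's median AL' against each vegetation group for
# the lower pair.
qai_from_scores <- function(scores, roster) {
  med <- function(cls) {
    s <- scores[scores$pair_class == cls, ]
    dt <- data.table::as.data.table(s)
    as.data.frame(dt[, list(al_prime = stats::median(al_prime)),
                     by = c("species_hi", "species_lo")])
  }
  up <- med("3-2"); lo <- med("2-1")
  rows <- list()
  for (i in seq_len(nrow(up))) {
    ins <- up$species_lo[i]
    lo_i <- lo[lo$species_hi == ins, ]
    if (!nrow(lo_i)) next
    lab <- classify_sync(lo_i$al_prime)
    summary21 <- paste0(
      if (sum(lab == "S")) paste0("S", sum(lab == "S")) else "",
      if (sum(lab == "S") && sum(lab == "A")) " " else "",
      if (sum(lab == "A")) paste0("A", sum(lab == "A")) else "")
    rows[[length(rows) + 1L]] <- data.frame(
      bird = up$species_hi[i], insect = ins,
      al32 = classify_sync(up$al_prime[i]), al21 = summary21,
      qai = qai(up$al_prime[i], stats::median(lo_i$al_prime)))
  }
  do.call(rbind, rows) %||%
    data.frame(bird = character(), insect = character(),
               al32 = character(), al21 = character(),
               qai = character())
}

stage_network <- function(config) {
  scores <- read_artefact(config, "al_scores.csv", "network")
  groups <- unique(c(scores$species_hi, scores$species_lo))
  roster <- data.frame(code = groups, common_name = groups,
                       group = "unknown", trophic_level = NA_integer_)
  for (mode in c("sync", "async")) {
    net <- build_network(scores, mode, roster)
    write_artefact(net$edges, config, paste0("network_", mode, ".csv"))
    write_network_graphml(net, artefact_path(
      config, paste0("network_", mode, ".graphml")))
  }
  invisible(config)
}

write_manifest <- function(config, stages) {
  files <- sort(list.files(config$out, pattern = "\\.csv$"))
  counts <- vapply(files, function(f)
    length(utils::count.fields(file.path(config$out, f), sep = ",",
                               quote = "\"")) - 1L,
    integer(1))
  cfg_path <- artefact_path(config, "config.json")
  write_config(config, cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    stages = stages,
    versions = list(r = as.character(getRversion()),
                    phenosync = as.character(
                      utils::packageVersion("phenosync"))),
    artefacts = lapply(stats::setNames(files, files), function(f)
      list(rows = unname(counts[[f]]),
           md5 = unname(tools::md5sum(file.path(config$out, f))))))
  jsonlite::write_json(manifest, artefact_path(config, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Validate an input file against a named schema
#'
#' Schema, range, duplicate and monotone-date checks for the CSV
#' dialects the pipeline consumes.  Known schemas: `hourly_weather`,
#' `daily_weather`, `ndvi`, `occurrences`, `events`.
#'
#' @param path CSV file.
#' @param schema_name one of the known schema names.
#' @return data.frame of issues (possibly empty) with columns `row`
#'   (NA for file-level issues) and `issue`.
#' @export
validate_inputs <- function(path, schema_name) {
  if (!file.exists(path)) stopf("cannot read %s", path)
  schemas <- list(
    hourly_weather = c("cell_id", "timestamp", "temp_c", "precip_mm"),
    daily_weather = c("cell_id", "date", "tmax", "tmin", "tppt"),
    ndvi = c("polygon_id", "date", "ndvi"),
    occurrences = c("species", "date", "x_km", "y_km"),
    events = c("species", "year", "cell_id", "event_day", "event_type"))
  if (!schema_name %in% names(schemas))
    stopf("unknown schema '%s'", schema_name)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  issues <- list()
  add <- function(row, issue)
    issues[[length(issues) + 1L]] <<- data.frame(row = row, issue = issue)
  miss <- setdiff(schemas[[schema_name]], names(df))
  if (length(miss)) {
    add(NA_integer_, paste("missing column(s):",
                           paste(miss, collapse = ", ")))
    return(do.call(rbind, issues))
  }
  if ("date" %in% names(df)) {
    d <- as.Date(df$date, optional = TRUE)
    bad <- which(is.na(d) & !is.na(df$date))
    for (r in bad) add(r, "unparseable date")
  }
  if (schema_name == "ndvi") {
    bad <- which(!is.na(df$ndvi) & (df$ndvi < -1 | df$ndvi > 1))
    for (r in bad) add(r, sprintf("ndvi %.3f outside [-1, 1]", df$ndvi[r]))
    key <- paste(df$polygon_id, df$date)
    for (r in which(duplicated(key))) add(r, "duplicate polygon-date")
  }
  if (schema_name == "occurrences") {
    bad <- which(is.na(df$x_km) | is.na(df$y_km))
    for (r in bad) add(r, "missing coordinate")
  }
  if (schema_name == "daily_weather") {
    bad <- which(!is.na(df$tppt) & df$tppt < 0)
    for (r in bad) add(r, "negative precipitation")
    bad <- which(!is.na(df$tmax) & !is.na(df$tmin) & df$tmax < df$tmin)
    for (r in bad) add(r, "tmax below tmin")
    key <- paste(df$cell_id, df$date)
    for (r in which(duplicated(key))) add(r, "duplicate cell-date")
  }
  if (schema_name == "events") {
    bad <- which(df$event_day < 1 | df$event_day > 366)
    for (r in bad) add(r, "event_day outside 1..366")
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(row = integer(), issue = character())
}
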