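#' @importFrom data.table data.table as.data.table is.data.table CJ
#'   setkeyv setorderv setnames fread fwrite := .N .SD
#' @importFrom stats median quantile
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  "obs_day", "ts", "temp_c", "precip_mm", "V1", "cell_id", "wmax",
  "wmin", "wppt", "tmax", "tmin", "tppt", "n_hours", "ndvi",
  "polygon_id", "month_mid", "ym", "mon", "event_day", "species",
  "n_sight", "year", "al", "al_prime", "pair_class", "species_hi",
  "species_lo", "..col"))
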