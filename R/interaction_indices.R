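# The interaction-index family: AL, standardised AL', QAI, the WO
# window-movement composite, IICWM with its three-way categorisation,
# and the synchrony/asynchrony network export.

#' Load the packaged species roster
#'
#' Thirty entries from the Irish woodland trophic-network case study:
#' 5 migrant birds (trophic level 3), 9 butterflies and 9 moths
#' (level 2), and 7 woodland vegetation groups (level 1).
#'
#' @return data.frame with columns `code`, `common_name`, `group`,
#'   `trophic_level`.
#' @export
species_roster <- function() {
  path <- system.file("extdata", "species_roster.csv",
                      package = "phenosync", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Load the packaged bird-insect IICWM classification table
#'
#' The 90 bird x insect rows of the case study's published
#' classification: qualitative AL' labels for the bird-insect level
#' (`al32`), the insect-vegetation synchrony summary (`al21`, e.g.
#' `"S7"` = synchronous with all 7 vegetation groups, `"S4 A3"` =
#' synchronous with 4 and asynchronous with 3), and the IICWM symbol.
#'
#' @return data.frame with columns `bird`, `insect`, `al32`, `al21`,
#'   `iicwm`.
#' @export
iicwm_classifications <- function() {
  path <- system.file("extdata", "iicwm_classifications.csv",
                      package = "phenosync", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
}

#' Signed day lag between two trophic levels (AL)
#'
#' `AL = event_hi - event_lo`, the day-of-year of the higher trophic
#' level's event minus the lower level's.  Positive means the higher
#' level follows the lower one (synchrony or delayed synchrony);
#' negative means it precedes it (asynchrony, e.g. birds arriving
#' before their insect prey takes flight).
#'
#' @param event_hi,event_lo event days-of-year, same year; vectorised.
#' @return numeric vector of signed day differences.
#' @export
al_index <- function(event_hi, event_lo) event_hi - event_lo

#' Min-max standardise AL values within a pooling group (AL')
#'
#' `AL' = (AL - min) / (max - min)` over the pool, mapping the pool
#' minimum to 0 (total asynchrony), the midpoint of a symmetric pool to
#' 0.5 (perfect synchrony) and the maximum to 1 (delayed synchrony).
#' Invariant under affine rescaling of the whole pool.
#'
#' @param al AL values to standardise.
#' @param pool values defining min and max; defaults to `al` itself.
#'   The conventional pool is all AL values of the same trophic
#'   pair class across species pairs and years.
#' @return AL' values in `[0, 1]`.
#' @export
standardize_al <- function(al, pool = al) {
  if (length(pool) < 2L) stopf("degenerate pool: need >= 2 AL values")
  lo <- min(pool); hi <- max(pool)
  if (hi <= lo) stopf("degenerate pool: max(AL) must exceed min(AL)")
  (al - lo) / (hi - lo)
}

#' Qualitative synchrony label from AL'
#'
#' `"A"` (asynchrony) when AL' < 0.5, `"S"` (synchrony) when
#' AL' >= 0.5; the boundary is synchronous.
#'
#' @param al_prime AL' values in `[0, 1]`; vectorised.
#' @return character vector of `"A"`/`"S"`.
#' @export
classify_sync <- function(al_prime) {
  if (any(is.na(al_prime)) || any(al_prime < 0 | al_prime > 1))
    stopf("al_prime must lie in [0, 1]")
  ifelse(al_prime < 0.5, "A", "S")
}

#' Qualitative integrated (a)synchrony index (QAI)
#'
#' Concatenates the synchrony labels of the upper (bird-insect) and
#' lower (insect-vegetation) interactions, each computed from the
#' median AL' over years: `"SS"`, `"SA"`, `"AS"` or `"AA"`.  `"AS"`
#' for example reads: green-up occurred before first flight, but first
#' flight occurred after the birds' arrival.
#'
#' @param al_prime_ab median AL' of the upper pair (levels 3-2).
#' @param al_prime_bc median AL' of the lower pair (levels 2-1).
#' @return character vector of two-letter categories.
#' @export
qai <- function(al_prime_ab, al_prime_bc) {
  paste0(classify_sync(al_prime_ab), classify_sync(al_prime_bc))
}

#' Window-open movement composite (WO)
#'
#' Sum over TMIN, TMAX and TPPT of the bird-minus-insect window-open
#' differences, in days.  Positive WO (scenario A): bird windows sit
#' further in the past and/or insect windows closer to first flight.
#' Negative WO (scenario B): the reverse.
#'
#' @param bird_wo,insect_wo named numeric vectors with elements
#'   `TMIN`, `TMAX`, `TPPT` (window-open days before the event).
#' @param drop_missing if `TRUE`, a variable missing (NA) on either
#'   side is dropped from both sides symmetrically instead of raising
#'   an error; the kept variables are recorded in the
#'   `"variables_used"` attribute.
#' @return signed days (scalar) with attribute `variables_used`.
#' @export
wo_composite <- function(bird_wo, insect_wo, drop_missing = FALSE) {
  vars <- c("TMIN", "TMAX", "TPPT")
  b <- bird_wo[vars]; i <- insect_wo[vars]
  bad <- is.na(b) | is.na(i)
  if (any(bad) && !drop_missing)
    stopf("missing window-open component(s): %s (set drop_missing = TRUE to drop symmetrically)",
          paste(vars[bad], collapse = ", "))
  use <- vars[!bad]
  if (!length(use)) stopf("no window-open components left")
  structure(sum(b[use] - i[use]), variables_used = use)
}

#' Interaction index of climate-window movement (IICWM)
#'
#' `IICWM = AL / WO` plus a three-symbol categorisation combining the
#' synchrony state with the window-movement scenario:
#' `"+"` synchronous (`AL >= 0`) under scenario A (`WO > 0`);
#' `"*"` asynchronous (`AL < 0`) under scenario B (`WO < 0`);
#' `"-"` the two mixed cases.  The value alone cannot distinguish
#' `"+"` from `"*"` (both ratios are positive), hence the symbol.
#'
#' @param al non-standardised AL, days; vectorised.
#' @param wo WO composite, days; must be nonzero.
#' @return data.frame with columns `value` and `category`.
#' @export
iicwm <- function(al, wo) {
  if (any(wo == 0))
    stopf("undefined ratio: WO = 0 (window movement cancels exactly); boundary case, no category assigned")
  category <- ifelse(al >= 0 & wo > 0, "+",
              ifelse(al < 0 & wo < 0, "*", "-"))
  data.frame(value = al / wo, category = category)
}

#' Score every cross-trophic species pair from national event dates
#'
#' Builds the AL table for all pairs with a strictly higher trophic
#' level on the left — bird-insect (3,2), bird-vegetation (3,1) and
#' insect-vegetation (2,1) — for every year both events are available,
#' then standardises within the chosen pool.
#'
#' @param summaries data.frame of national event dates per species-year
#'   with columns `species`, `year` and `median` (as from
#'   [summarize_events()]) or `event_day`.
#' @param roster roster data.frame (default the packaged one).
#' @param pool `"pair_class"` (default; all AL of the same trophic pair
#'   class across species pairs and years share min/max) or
#'   `"species_pair"`.
#' @return data.frame of interaction scores: `species_hi`,
#'   `species_lo`, `pair_class`, `year`, `al`, `al_prime`.
#' @export
al_scores <- function(summaries, roster = species_roster(),
                      pool = c("pair_class", "species_pair")) {
  pool <- match.arg(pool)
  assert_cols(summaries, c("species", "year"), "summaries")
  day_col <- if ("median" %in% names(summaries)) "median" else "event_day"
  assert_cols(summaries, day_col, "summaries")
  s <- merge(summaries[, c("species", "year", day_col)],
             roster[, c("code", "trophic_level")],
             by.x = "species", by.y = "code")
  if (nrow(s) == 0L)
    stopf("no summarised species matched the roster codes")
  pairs <- merge(s, s, by = "year", suffixes = c("_hi", "_lo"))
  pairs <- pairs[pairs$trophic_level_hi > pairs$trophic_level_lo, ]
  out <- data.frame(
    species_hi = pairs[[paste0("species", "_hi")]],
    species_lo = pairs[[paste0("species", "_lo")]],
    pair_class = paste0(pairs$trophic_level_hi, "-",
                        pairs$trophic_level_lo),
    year = pairs$year,
    al = al_index(pairs[[paste0(day_col, "_hi")]],
                  pairs[[paste0(day_col, "_lo")]]))
  key <- if (pool == "pair_class") out$pair_class
         else paste(out$species_hi, out$species_lo)
  out$al_prime <- stats::ave(out$al, key,
                             FUN = function(v) standardize_al(v))
  attr(out, "pooling") <- pool
  out[order(out$pair_class, out$species_hi, out$species_lo, out$year), ]
}

#' Enumerate cross-trophic pair combinations of a roster
#'
#' All ordered higher/lower trophic-level pairs.  For the packaged
#' roster: 90 bird-insect (3,2), 126 insect-vegetation (2,1) and 35
#' bird-vegetation (3,1) pairs — 251 in total.
#'
#' @param roster roster data.frame.
#' @return data.frame `species_hi`, `species_lo`, `pair_class`.
#' @export
enumerate_pairs <- function(roster = species_roster()) {
  g <- expand.grid(hi = roster$code, lo = roster$code,
                   stringsAsFactors = FALSE)
  lv <- stats::setNames(roster$trophic_level, roster$code)
  g <- g[lv[g$hi] > lv[g$lo], ]
  out <- data.frame(species_hi = g$hi, species_lo = g$lo,
                    pair_class = paste0(lv[g$hi], "-", lv[g$lo]))
  rownames(out) <- NULL
  out
}

#' Synchrony or asynchrony network as a weighted edge list
#'
#' Splits pairs by their median AL' at the 0.5 boundary (boundary goes
#' to the synchrony network).  Sync-mode weight is
#' `1 - 2 * |AL' - 0.5|`: maximal (1) at perfect synchrony, thinning
#' towards delayed synchrony.  Async-mode weight is `1 - 2 * AL'`:
#' maximal at total asynchrony.  Node attributes carry the trophic
#' level for colouring.
#'
#' @param scores interaction scores (see [al_scores()]); the median
#'   AL' per pair over years defines the edge.
#' @param mode `"sync"` or `"async"`.
#' @param roster roster used for node attributes.
#' @return list with `edges` (source, target, al_prime, weight, mode)
#'   and `nodes` (code, group, trophic_level).
#' @export
build_network <- function(scores, mode = c("sync", "async"),
                          roster = species_roster()) {
  mode <- match.arg(mode)
  assert_cols(scores, c("species_hi", "species_lo", "al_prime"),
              "scores")
  dt <- data.table::as.data.table(scores)
  med <- dt[, list(al_prime = stats::median(al_prime)),
            by = c("species_hi", "species_lo")]
  keep <- if (mode == "sync") med$al_prime >= 0.5 else med$al_prime < 0.5
  med <- med[keep]
  weight <- if (mode == "sync") 1 - 2 * abs(med$al_prime - 0.5)
            else 1 - 2 * med$al_prime
  edges <- data.frame(source = med$species_hi, target = med$species_lo,
                      al_prime = med$al_prime, weight = weight,
                      mode = mode)
  used <- unique(c(edges$source, edges$target))
  nodes <- roster[roster$code %in% used,
                  c("code", "group", "trophic_level")]
  list(edges = edges[order(edges$source, edges$target), ],
       nodes = nodes)
}

#' Export a network to GraphML
#'
#' @param network result of [build_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Tally IICWM categories and fully synchronous relationships
#'
#' Histogram of the `+` / `-` / `*` symbols plus the count of "fully
#' synchronous" rows, defined as: the bird-insect label is `S` and the
#' insect shows synchrony with at least one vegetation group (the
#' `al21` summary contains an `S`).
#'
#' @param table classification table in the layout of
#'   [iicwm_classifications()]; defaults to the packaged one.
#' @return list with `categories` (named counts over `+`, `-`, `*`)
#'   and `fully_synchronous`.
#' @export
tally_classifications <- function(table = iicwm_classifications()) {
  assert_cols(table, c("bird", "insect", "al32", "al21", "iicwm"),
              "table")
  if (nrow(table) > 0 &&
      !all(table$iicwm %in% c("+", "-", "*")))
    stopf("schema error: iicwm symbols must be one of +, -, *")
  if (nrow(table) > 0 && !all(table$al32 %in% c("A", "S")))
    stopf("schema error: al32 labels must be A or S")
  cats <- c(`+` = sum(table$iicwm == "+"),
            `-` = sum(table$iicwm == "-"),
            `*` = sum(table$iicwm == "*"))
  fully <- sum(table$al32 == "S" & grepl("S", table$al21, fixed = TRUE))
  list(categories = cats, fully_synchronous = fully)
}
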