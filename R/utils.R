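# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates
#' `expr`, and restores the previous RNG state on exit.  All generators
#' in the package route their randomness through this helper so that a
#' call is a pure function of its arguments.
#'
#' @param seed integer scalar.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage substream seed from a run seed.  Kept below 2^31-1.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(stream) * 7919L
}

# Day-of-year with 1 January = day 1.
doy <- function(date) as.integer(format(date, "%j"))

# Calendar date from (year, day-of-year).
date_from_doy <- function(year, day) {
  as.Date(paste0(year, "-01-01")) + (as.integer(day) - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}
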