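# Internal helpers. All temporal logic works on whole calendar days; dates
# are R Date objects and window arithmetic is integer-day arithmetic.

DAYS_PER_YEAR <- 365.25

#' Run code with a temporary RNG seed
#'
#' Restores (or removes) the global \code{.Random.seed} afterwards so that
#' seeded package operations do not disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Parse ISO-8601 dates, reporting the offending row index on failure.
parse_iso_dates <- function(x, table, column, allow_na = FALSE) {
  x <- as.character(x)
  blank <- is.na(x) | !nzchar(trimws(x))
  out <- as.Date(rep(NA_character_, length(x)))
  if (any(!blank)) {
    parsed <- as.Date(x[!blank], format = "%Y-%m-%d", optional = TRUE)
    bad <- is.na(parsed)
    if (any(bad)) {
      row <- which(!blank)[which(bad)[1L]]
      stop(sprintf("table '%s', column '%s': unparseable date '%s' at row %d",
                   table, column, x[!blank][which(bad)[1L]], row), call. = FALSE)
    }
    out[!blank] <- parsed
  }
  if (!allow_na && any(blank)) {
    stop(sprintf("table '%s', column '%s': missing date at row %d",
                 table, column, which(blank)[1L]), call. = FALSE)
  }
  out
}

# Number of days in [lo, hi] (inclusive) covered by merged spans.
covered_days <- function(spans, lo, hi) {
  if (nrow(spans) == 0L || hi < lo) return(0L)
  s <- pmax(as.integer(spans$start_date), as.integer(lo))
  e <- pmin(as.integer(spans$end_date), as.integer(hi))
  sum(pmax(e - s + 1L, 0L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
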