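# Timestamp handling. MIMIC-style exports carry naive local datetimes
# ("2131-05-04 19:08:00"); there is no timezone information, so everything is
# parsed as UTC and treated as wall-clock time. Relative times are float hours
# from admission.

#' Parse MIMIC-style timestamp strings
#'
#' Accepts `"YYYY-MM-DD HH:MM:SS"` (full timestamp) and `"YYYY-MM-DD"`
#' (date only). Date-only values are placed at midnight and flagged via the
#' `date_only` attribute so downstream logic can treat them conservatively.
#'
#' @param x character vector of timestamp strings (`NA`/empty allowed).
#' @return `POSIXct` vector (UTC) with a logical attribute `date_only`
#'   marking rows that carried no time component.
#' @export
parse_ts <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  full <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  dateonly <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d")
  out <- full
  use_date <- is.na(full) & !is.na(dateonly)
  out[use_date] <- dateonly[use_date]
  attr(out, "date_only") <- use_date & !is.na(x)
  out
}

#' Hours elapsed between two timestamps
#'
#' @param ts,origin `POSIXct` vectors (recycled).
#' @return numeric hours (`ts - origin`).
#' @export
hours_since <- function(ts, origin) {
  as.numeric(difftime(ts, origin, units = "hours"))
}

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
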