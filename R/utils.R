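# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round a percentage half-up to the nearest integer
#'
#' Percentages in printed summaries are rounded half-up (0.5 always rounds
#' away from zero), matching the convention of field reports, rather than
#' base R's round-half-even.
#'
#' @param x Numeric vector of percentages.
#' @return Integer vector.
#' @keywords internal
pct_round <- function(x) as.integer(floor(x + 0.5))

#' Parse strict ISO 8601 UTC timestamps
#'
#' Accepts only `YYYY-MM-DDTHH:MM:SSZ` (or `+00:00`); timezone-naive input is
#' rejected so that event grouping can never silently mix clocks.
#'
#' @param x Character vector.
#' @return POSIXct vector in UTC.
#' @keywords internal
parse_timestamp <- function(x) {
  x <- as.character(x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}(Z|\\+00:00)$", x)
  if (!all(ok)) {
    stop("timezone-naive or malformed timestamp(s): ",
         paste(utils::head(x[!ok], 5L), collapse = ", "),
         call. = FALSE)
  }
  out <- as.POSIXct(sub("(Z|\\+00:00)$", "", x),
                    format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(out)) stop("unparseable timestamp(s)", call. = FALSE)
  out
}

#' @keywords internal
format_timestamp <- function(t) {
  format(t, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# semicolon-joined integer sets, e.g. clip positions "1;3;4"
join_positions <- function(p) vapply(p, function(v) paste(sort(unique(v)), collapse = ";"), "")
split_positions <- function(s) lapply(strsplit(as.character(s), ";", fixed = TRUE), as.integer)
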