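#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse ISO-8601 timestamps
#'
#' Accepts `YYYY-MM-DD`, `YYYY-MM-DDTHH:MM:SS`, with optional fractional
#' seconds, trailing `Z`, or a numeric UTC offset. Naive timestamps (no zone
#' designator) are interpreted as UTC so that parsing is deterministic across
#' machines.
#'
#' @param x character vector of timestamps.
#' @return `POSIXct` vector in UTC; `NA` where unparseable.
#' @export
parse_iso8601 <- function(x) {
  one <- function(s) {
    if (is.null(s) || is.na(s) || !nzchar(s)) return(NA_real_)
    s <- trimws(s)
    if (grepl("^\\d{4}-\\d{2}-\\d{2}$", s)) {
      out <- as.POSIXct(s, tz = "UTC", format = "%Y-%m-%d")
      return(as.numeric(out))
    }
    # offset form +HH:MM must lose the colon for %z
    if (grepl("[+-]\\d{2}:\\d{2}$", s)) {
      s <- sub("([+-]\\d{2}):(\\d{2})$", "\\1\\2", s)
      out <- as.POSIXct(s, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS%z")
      return(as.numeric(out))
    }
    s <- sub("Z$", "", s)
    if (!grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?$", s)) {
      return(NA_real_)
    }
    fmt <- if (grepl(":\\d{2}(\\.\\d+)?$", sub("^.*T", "", s)) &&
               lengths(regmatches(s, gregexpr(":", s))) == 2) {
      "%Y-%m-%dT%H:%M:%OS"
    } else {
      "%Y-%m-%dT%H:%M"
    }
    as.numeric(as.POSIXct(s, tz = "UTC", format = fmt))
  }
  vapply(as.character(x), one, numeric(1), USE.NAMES = FALSE) |>
    as.POSIXct(tz = "UTC", origin = "1970-01-01")
}

#' Format a timestamp as ISO-8601 UTC
#' @param t POSIXct.
#' @return character, `YYYY-MM-DDTHH:MM:SSZ`.
#' @export
format_iso8601 <- function(t) {
  format(as.POSIXct(t, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# classed condition so callers can distinguish validation, parse, contract and
# not-found failures programmatically
cdskit_abort <- function(message, class) {
  stop(structure(
    class = c(class, "cdskit_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

ext_file <- function(...) {
  path <- system.file("extdata", ..., package = "cdskit")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ may not be installed yet
    path <- file.path("inst", "extdata", ...)
  }
  path
}

read_table_file <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
}
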