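#' Timestamped water-quality sample series
#'
#' `sample_series()` is the package's universal data container: one variable at
#' one site, as a data frame with columns `timestamp` (POSIXct), `value`
#' (numeric) and `flag` (character QC code, `""` = retained). Site, variable
#' and units travel as attributes. Rows are sorted by timestamp.
#'
#' @param timestamp POSIXct (or coercible) vector of observation times.
#' @param value numeric vector of observed values.
#' @param site short site code.
#' @param variable one of `"temperature"`, `"salinity"`, `"do"`, `"chl"`,
#'   `"log10chl"`, `"aou"` (other labels are accepted with their own `units`).
#' @param flag character QC codes; `""` marks a retained sample.
#' @param units measurement units; defaults to the conventional unit for a
#'   known `variable` (degC, psu, mg/L, ug/L, log10(ug/L), mg/L).
#'
#' @return An object of class `sample_series` (a data frame).
#' @export
sample_series <- function(timestamp, value, site = "SITE",
                          variable = "temperature", flag = NULL,
                          units = NULL) {
  if (!inherits(timestamp, "POSIXct")) {
    timestamp <- as.POSIXct(timestamp, tz = "UTC")
  }
  value <- as.numeric(value)
  if (length(timestamp) != length(value)) {
    stop("timestamp and value must have equal length")
  }
  if (is.null(flag)) flag <- rep("", length(value))
  ord <- order(timestamp)
  x <- data.frame(timestamp = timestamp[ord], value = value[ord],
                  flag = as.character(flag)[ord],
                  stringsAsFactors = FALSE)
  if (is.null(units)) units <- variable_units(variable)
  structure(x, class = c("sample_series", "data.frame"),
            site = site, variable = variable, units = units)
}

variable_units <- function(variable) {
  switch(variable,
         temperature = "degC", salinity = "psu", do = "mg/L",
         chl = "ug/L", log10chl = "log10(ug/L)", aou = "mg/L",
         "unknown")
}

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("<sample_series> site=%s variable=%s units=%s n=%d\n",
              attr(x, "site"), attr(x, "variable"), attr(x, "units"),
              nrow(x)))
  if (nrow(x) > 0) {
    cat(sprintf("  span: %s .. %s\n", format(min(x$timestamp)),
                format(max(x$timestamp))))
    print(utils::head(as.data.frame(x), 5L))
    if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  }
  invisible(x)
}

# rebuild a sample_series from a subset of rows, keeping metadata
series_like <- function(template, rows) {
  structure(as.data.frame(rows),
            class = c("sample_series", "data.frame"),
            site = attr(template, "site"),
            variable = attr(template, "variable"),
            units = attr(template, "units"))
}

is_leap <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

#' Day of year in the 365-day climatological calendar
#'
#' Maps timestamps to day of year 1..365. In leap years Feb 29 is assigned day
#' 60 and every later date keeps the day number it has in a non-leap year, so
#' the annual period is exactly 365 days for every year.
#'
#' @param timestamp POSIXct or Date vector.
#' @return Integer day of year in 1..365.
#' @export
day_of_year365 <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  yday <- lt$yday + 1L            # POSIXlt yday is 0-based
  leap <- is_leap(lt$year + 1900L)
  yday - as.integer(leap & yday > 60L)
}

# continuous time in years since the first timestamp (365.25-day year)
years_since <- function(timestamp, origin = min(timestamp)) {
  as.numeric(difftime(timestamp, origin, units = "days")) / 365.25
}

# calendar quarter 1..4 (Jan-Mar, Apr-Jun, Jul-Sep, Oct-Dec)
calendar_quarter <- function(timestamp) {
  (as.POSIXlt(timestamp)$mon %/% 3L) + 1L
}

# run code with a private RNG stream seeded by `seed`, restoring caller state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# circular difference of day-of-year values, reported in (-182.5, 182.5]
circ_day_diff <- function(late, early, period = 365) {
  d <- (late - early) %% period
  ifelse(d > period / 2, d - period, d)
}
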