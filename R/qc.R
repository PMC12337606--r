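#' Spike filter against the preceding retained point
#'
#' Removes a sample when it jumps more than one standard deviation away from
#' the previously retained sample, the SD being computed from the raw values of
#' the sample's own calendar year. The first sample is always kept, and each
#' comparison is made against the last *retained* point, so an isolated spike
#' does not shield its successors.
#'
#' @param series a `sample_series`, sorted by time.
#' @param yearly_sd optional named numeric vector of per-year SDs (names =
#'   calendar years). Defaults to the SD of the raw values in each year.
#' @return A list with `series` (retained samples) and `report` (a `qc_report`).
#' @export
spike_filter <- function(series, yearly_sd = NULL) {
  n <- nrow(series)
  if (n < 2) {
    warning("series has < 2 points; spike filter skipped")
    return(list(series = series,
                report = qc_report(n, 0L, 0L, rep("", n))))
  }
  yr <- as.POSIXlt(series$timestamp)$year + 1900L
  if (is.null(yearly_sd)) {
    yearly_sd <- tapply(series$value, yr, stats::sd)
    yearly_sd[is.na(yearly_sd)] <- Inf    # single-obs years: cannot screen
  }
  sdv <- yearly_sd[as.character(yr)]
  flags <- rep("", n)
  last <- series$value[1]
  for (i in 2:n) {
    if (abs(series$value[i] - last) > sdv[i]) {
      flags[i] <- "spike"
    } else {
      last <- series$value[i]
    }
  }
  keep <- flags == ""
  list(series = series_like(series, series[keep, , drop = FALSE]),
       report = qc_report(n, sum(!keep), 0L, flags))
}

#' Chauvenet's criterion outlier screen
#'
#' A sample is rejected when, under a normal model fitted to all values, fewer
#' than half an observation that extreme is expected in the record:
#' `n * P(|Z| > |z_i|) < 0.5` with `z_i = (y_i - mean) / SD`. The default is a
#' single pass; `iterate = TRUE` repeats the screen on the retained values
#' until no further rejection (the literature uses both conventions).
#'
#' @param values numeric vector, length >= 4.
#' @param iterate repeat to convergence? Default `FALSE` (single pass).
#' @return A list with `mask` (logical, `TRUE` = rejected) and `report`.
#' @export
chauvenet_screen <- function(values, iterate = FALSE) {
  n <- length(values)
  if (n < 4) {
    warning("Chauvenet screen needs n >= 4; nothing rejected")
    return(list(mask = rep(FALSE, n),
                report = qc_report(n, 0L, 0L, rep("", n))))
  }
  mask <- rep(FALSE, n)
  repeat {
    kept <- values[!mask]
    m <- mean(kept); s <- stats::sd(kept)
    if (!is.finite(s) || s == 0) break
    z <- abs(values - m) / s
    reject <- !mask & (length(kept) * 2 * stats::pnorm(-z) < 0.5)
    if (!any(reject)) break
    mask <- mask | reject
    if (!iterate) break
  }
  flags <- ifelse(mask, "chauvenet", "")
  list(mask = mask, report = qc_report(n, 0L, sum(mask), flags))
}

#' Base-10 logarithm transform for chlorophyll-a
#'
#' Nonpositive values cannot be log-transformed; they are dropped and counted.
#'
#' @param series a `sample_series` of chlorophyll-a (ug/L).
#' @return A list with `series` (variable `log10chl`) and `report`.
#' @export
log10_chl <- function(series) {
  bad <- series$value <= 0
  kept <- series[!bad, , drop = FALSE]
  out <- sample_series(kept$timestamp, log10(kept$value),
                       site = attr(series, "site"), variable = "log10chl",
                       flag = kept$flag)
  flags <- ifelse(bad, "nonpositive", "")
  list(series = out,
       report = qc_report(nrow(series), 0L, 0L, flags,
                          n_dropped_other = sum(bad)))
}

#' Daily averaging of a sub-daily series
#'
#' Each calendar day's value is the arithmetic mean of that day's retained
#' samples; days without samples are absent from the output, never zero-filled.
#' Daily averaging removes the diurnal cycle from high-frequency sonde data.
#'
#' @param series a `sample_series` at sub-daily cadence.
#' @param min_samples minimum samples for a valid daily mean (default 1).
#' @return A `sample_series` with one value per day (timestamp = local noon)
#'   and an `n_samples` column recording each day's sample count.
#' @export
daily_average <- function(series, min_samples = 1L) {
  day <- as.Date(series$timestamp, tz = "UTC")
  agg <- stats::aggregate(series$value, by = list(day = day),
                          FUN = function(v) c(mean(v), length(v)))
  means <- agg$x[, 1]
  counts <- as.integer(agg$x[, 2])
  keep <- counts >= min_samples
  out <- sample_series(as.POSIXct(paste(agg$day[keep], "12:00:00"),
                                  tz = "UTC"),
                       means[keep],
                       site = attr(series, "site"),
                       variable = attr(series, "variable"),
                       units = attr(series, "units"))
  out$n_samples <- counts[keep]
  out
}

#' QC bookkeeping record
#'
#' Counts reconcile: `n_out = n_in - n_flagged_spike - n_flagged_chauvenet -
#' n_dropped_other`.
#'
#' @param n_in,n_flagged_spike,n_flagged_chauvenet counts.
#' @param flags per-sample QC codes (`""` = retained).
#' @param n_dropped_other samples dropped for other reasons (e.g. nonpositive
#'   chlorophyll before a log transform).
#' @return A `qc_report` list.
#' @export
qc_report <- function(n_in, n_flagged_spike, n_flagged_chauvenet, flags,
                      n_dropped_other = 0L) {
  structure(list(n_in = as.integer(n_in),
                 n_flagged_spike = as.integer(n_flagged_spike),
                 n_flagged_chauvenet = as.integer(n_flagged_chauvenet),
                 n_dropped_other = as.integer(n_dropped_other),
                 n_out = as.integer(n_in - n_flagged_spike -
                                      n_flagged_chauvenet - n_dropped_other),
                 flags = flags),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> in=%d spike=%d chauvenet=%d other=%d out=%d\n",
    x$n_in, x$n_flagged_spike, x$n_flagged_chauvenet, x$n_dropped_other,
    x$n_out))
  invisible(x)
}
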