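#' Read a sample series from CSV
#'
#' Expects a header with at least `timestamp` and `value`; `site`, `variable`
#' and `flag` columns are honoured when present. Unknown columns are ignored
#' with a warning. Rows whose timestamp does not parse (ISO 8601) or whose
#' value is not numeric are rejected and counted; out-of-order rows are sorted
#' with a warning.
#'
#' @param path CSV file path.
#' @param site,variable fallbacks when the file lacks those columns.
#' @return A `sample_series`; the number of rejected rows is attached as
#'   attribute `n_rejected` and rejected line numbers as `rejected_lines`.
#' @export
read_series <- function(path, site = NULL, variable = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("timestamp", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  known <- c("site", "variable", "timestamp", "value", "flag")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warning(sprintf("ignoring unknown column(s): %s",
                    paste(extra, collapse = ", ")))
  }
  ts <- parse_timestamps(raw$timestamp)
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- is.na(ts) | is.na(val)
  if (any(bad)) {
    message(sprintf("rejected %d malformed row(s) at line(s): %s",
                    sum(bad),
                    paste(utils::head(which(bad) + 1L, 10), collapse = ", ")))
  }
  if (is.unsorted(ts[!bad])) warning("timestamps out of order; sorting")
  out <- sample_series(
    ts[!bad], val[!bad],
    site = if (!is.null(site)) site else
      if ("site" %in% names(raw)) raw$site[!bad][1] else "SITE",
    variable = if (!is.null(variable)) variable else
      if ("variable" %in% names(raw)) raw$variable[!bad][1] else "unknown",
    flag = if ("flag" %in% names(raw)) raw$flag[!bad] else NULL)
  attr(out, "n_rejected") <- sum(bad)
  attr(out, "rejected_lines") <- which(bad) + 1L
  out
}

#' Write a sample series to CSV
#'
#' Columns: site, variable, timestamp (ISO 8601, UTC), value, flag.
#' `read_series(write_series(x))` is value-identical.
#'
#' @param series a `sample_series`. @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  df <- data.frame(site = attr(series, "site"),
                   variable = attr(series, "variable"),
                   timestamp = format(series$timestamp,
                                      "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   value = series$value,
                   flag = series$flag)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a harmonic fit (and optional composite summary / CIs) as JSON
#'
#' @param fit a `harmonic_fit`. @param path output path.
#' @param summary optional `composite_summary`. @param ci optional
#'   `bootstrap_ci`.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, summary = NULL, ci = NULL) {
  out <- unclass(fit)
  if (!is.null(summary)) out$composite <- unclass(summary)
  if (!is.null(ci)) {
    out$ci <- list(level = ci$level, n_boot = ci$n_boot, seed = ci$seed,
                   elements = as.data.frame(ci$ci))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Fitted daily composite curve as a data frame
#'
#' @param fit a `harmonic_fit`.
#' @return 365-row data frame `doy`, `fitted`.
#' @export
fitted_curve <- function(fit) {
  data.frame(doy = 1:365, fitted = predict(fit, 1:365))
}

#' Run the full analysis pipeline on a set of series
#'
#' Sequences the analysis stages: QC (spike filter, Chauvenet screen, log10
#' chlorophyll, daily averaging of sub-daily records), AOU derivation when
#' temperature, salinity and dissolved oxygen share a time base, harmonic
#' fitting with bootstrap CIs and composite extrema, GLS trend on
#' deseasonalized anomalies, and (optionally) the subsampling experiments.
#' Re-running with the same config and inputs reproduces every output.
#'
#' @param series named list of `sample_series` (names are variable labels;
#'   recognised: `temperature`, `salinity`, `do`, `chl`).
#' @param config list of options: `seed` (integer, default 1), `n_boot`
#'   (default 1000), `daily_average` (logical; apply to sub-daily series),
#'   `chauvenet` (logical, default TRUE), `spike_filter` (logical, default
#'   TRUE), `trend` (logical, default TRUE), `subsampling` (NULL to skip, or a
#'   list with `counts_per_quarter`, `n_yrs_grid`, `n_trials`),
#'   `out_dir` (NULL for no files). A path to a JSON or YAML config file is
#'   also accepted.
#' @return A named list per variable with `qc`, `fit`, `summary`, `ci`,
#'   `trend`, plus `aou` results when derivable and `subsampling` when
#'   requested, and a `log` recording seeds and options.
#' @export
run_pipeline <- function(series, config = list()) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(list(seed = 1L, n_boot = 1000,
                                daily_average = TRUE, chauvenet = TRUE,
                                spike_filter = TRUE, trend = TRUE,
                                subsampling = NULL, out_dir = NULL), config)
  log <- list(seed = cfg$seed, n_boot = cfg$n_boot,
              options = cfg[setdiff(names(cfg), "out_dir")])
  # --- QC stage ---
  qc_stage <- lapply(names(series), function(v) {
    s <- series[[v]]
    rep_list <- list()
    if (isTRUE(cfg$spike_filter) && nrow(s) >= 2) {
      sf <- spike_filter(s)
      s <- sf$series; rep_list$spike <- sf$report
    }
    if (v == "chl") {
      lg <- log10_chl(s)
      s <- lg$series; rep_list$log10 <- lg$report
    }
    if (isTRUE(cfg$chauvenet) && nrow(s) >= 4) {
      ch <- chauvenet_screen(s$value)
      rep_list$chauvenet <- ch$report
      s <- series_like(s, s[!ch$mask, , drop = FALSE])
    }
    cad <- stats::median(diff(as.numeric(s$timestamp)))
    if (isTRUE(cfg$daily_average) && is.finite(cad) && cad < 86400) {
      s <- daily_average(s)
    }
    list(series = s, reports = rep_list)
  })
  names(qc_stage) <- ifelse(names(series) == "chl", "log10chl", names(series))
  # --- AOU stage (requires shared time base) ---
  vars <- names(qc_stage)
  if (all(c("temperature", "salinity", "do") %in% vars)) {
    tt <- qc_stage$temperature$series
    ss <- qc_stage$salinity$series
    dd <- qc_stage$do$series
    shared <- Reduce(intersect, list(as.numeric(tt$timestamp),
                                     as.numeric(ss$timestamp),
                                     as.numeric(dd$timestamp)))
    if (length(shared) >= 12) {
      pick <- function(x) series_like(x, x[as.numeric(x$timestamp) %in%
                                             shared, , drop = FALSE])
      aou_s <- derive_aou_series(pick(tt), pick(ss), pick(dd))
      qc_stage$aou <- list(series = aou_s, reports = list())
    }
  }
  # --- harmonic + trend stage ---
  results <- lapply(names(qc_stage), function(v) {
    s <- qc_stage[[v]]$series
    clim <- to_climatology(s)
    fit <- fit_harmonics(clim)
    ci <- bootstrap_fit(clim, n_boot = cfg$n_boot, seed = cfg$seed)
    out <- list(qc = qc_stage[[v]]$reports, series = s, fit = fit,
                summary = composite_extrema(fit), ci = ci)
    span <- as.numeric(diff(range(s$timestamp)), units = "days") / 365.25
    if (isTRUE(cfg$trend) && span >= 3 && nrow(s) >= 12) {
      out$trend <- gls_trend(deseasonalize(s, fit))
    }
    out
  })
  names(results) <- names(qc_stage)
  # --- subsampling stage ---
  if (!is.null(cfg$subsampling)) {
    sub <- cfg$subsampling
    results$subsampling <- lapply(names(qc_stage), function(v) {
      s <- qc_stage[[v]]$series
      ref <- reference_fit(s, n_boot = cfg$n_boot, seed = cfg$seed)
      dens <- if (!is.null(sub$counts_per_quarter)) {
        subsample_density(ref, sub$counts_per_quarter,
                          n_trials = sub$n_trials %||% 200, seed = cfg$seed)
      }
      dur <- sweep_duration(ref,
                            n_yrs_grid = sub$n_yrs_grid %||%
                              c(5, 10, 15, 20, 25, 30, 40, 50),
                            n_trials = sub$n_trials %||% 200, seed = cfg$seed)
      list(reference = ref, density = dens, duration = dur,
           min_duration = minimum_duration(dur))
    })
    names(results$subsampling) <- names(qc_stage)
  }
  results$log <- log
  # --- optional file outputs ---
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(results, cfg$out_dir)
  results
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ISO 8601 variants; unparseable entries become NA rather than errors
parse_timestamps <- function(x) {
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"))
  }
  out
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (v in setdiff(names(results), c("log", "subsampling"))) {
    r <- results[[v]]
    write_series(r$series, file.path(out_dir, paste0(v, "_series.csv")))
    write_fit_json(r$fit, file.path(out_dir, paste0(v, "_fit.json")),
                   summary = r$summary, ci = r$ci)
    utils::write.csv(fitted_curve(r$fit),
                     file.path(out_dir, paste0(v, "_curve.csv")),
                     row.names = FALSE)
    if (!is.null(r$trend)) {
      utils::write.csv(trend_table(stats::setNames(list(r$trend), v)),
                       file.path(out_dir, paste0(v, "_trend.csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(results$subsampling)) {
    for (v in names(results$subsampling)) {
      sb <- results$subsampling[[v]]
      utils::write.csv(cbind(variable = v, sb$duration$table),
                       file.path(out_dir, paste0(v, "_duration.csv")),
                       row.names = FALSE)
      jsonlite::write_json(sb$min_duration,
                           file.path(out_dir, paste0(v, "_min_duration.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  jsonlite::write_json(results$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
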