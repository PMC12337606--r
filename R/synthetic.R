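#' Configuration for a synthetic water-quality series
#'
#' Ground-truth parameters of a simulated record: an annual and a semi-annual
#' harmonic (amplitudes `amp1`, `amp2` in variable units, maxima at days of
#' year `dmax1`, `dmax2`), a linear trend (units per year), an optional diurnal
#' cycle (sonde mode), AR(1) noise on the sampling grid, missing-data windows,
#' and randomly placed spikes. The AR(1) coefficient `ar1_rho` is per sampling
#' step: a per-step rho of r at 15-min cadence corresponds to a per-day
#' autocorrelation of r^96.
#'
#' @param mean long-term mean (variable units).
#' @param amp1,amp2 harmonic amplitudes, >= 0.
#' @param dmax1,dmax2 day of year of each harmonic's maximum, in [1, 365].
#' @param trend linear trend, units per year.
#' @param ar1_rho AR(1) coefficient of the noise, |rho| < 1.
#' @param noise_sd innovation SD of the AR(1) noise (units).
#' @param diurnal_amp amplitude of a 24-h cosine (units), >= 0; use for
#'   sonde-like series only.
#' @param diurnal_peak_hour local hour of the diurnal maximum (default 15).
#' @param cadence sampling interval: `"15 min"`, `"1 hour"`, `"1 day"`, or
#'   `"quarterly"`.
#' @param start,end first and last calendar date (Date or string).
#' @param sample_hour hour of day at which quarterly/daily samples are taken
#'   (mimics a field protocol anchored to a consistent time of day).
#' @param gap_spec list of `c(start, end)` date pairs to remove (gaps).
#' @param spike_rate fraction of samples replaced by spikes, in [0, 0.1).
#' @param spike_scale spike magnitude as a multiple of `noise_sd`.
#' @param seed integer seed.
#' @param variable,site labels for the generated series.
#' @return A validated `syn_config` list.
#' @export
synthetic_config <- function(mean = 15, amp1 = 5, amp2 = 0,
                             dmax1 = 200, dmax2 = 100,
                             trend = 0, ar1_rho = 0, noise_sd = 0,
                             diurnal_amp = 0, diurnal_peak_hour = 15,
                             cadence = "1 day",
                             start = "2010-01-01", end = "2019-12-31",
                             sample_hour = 10,
                             gap_spec = list(),
                             spike_rate = 0, spike_scale = 6,
                             seed = 1L,
                             variable = "temperature", site = "SYN") {
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop("end must follow start")
  if (amp1 < 0 || amp2 < 0 || diurnal_amp < 0) {
    stop("amplitudes must be >= 0")
  }
  if (dmax1 < 1 || dmax1 > 365 || dmax2 < 1 || dmax2 > 365) {
    stop("dmax must lie in [1, 365]")
  }
  if (abs(ar1_rho) >= 1) stop("|ar1_rho| must be < 1")
  if (spike_rate < 0 || spike_rate >= 0.1) stop("spike_rate must be in [0, 0.1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!cadence %in% c("15 min", "1 hour", "1 day", "quarterly")) {
    stop("cadence must be one of '15 min', '1 hour', '1 day', 'quarterly'")
  }
  structure(list(mean = mean, amp1 = amp1, amp2 = amp2,
                 dmax1 = dmax1, dmax2 = dmax2, trend = trend,
                 ar1_rho = ar1_rho, noise_sd = noise_sd,
                 diurnal_amp = diurnal_amp,
                 diurnal_peak_hour = diurnal_peak_hour,
                 cadence = cadence, start = start, end = end,
                 sample_hour = sample_hour, gap_spec = gap_spec,
                 spike_rate = spike_rate, spike_scale = spike_scale,
                 seed = as.integer(seed),
                 variable = variable, site = site),
            class = "syn_config")
}

# sampling grid implied by a config; quarterly sampling is anchored near each
# quarter's midpoint with seeded scheduling jitter (field visits are never on
# the same calendar day every year), at a fixed local time of day
syn_time_grid <- function(config) {
  t0 <- as.POSIXct(paste(config$start,
                         sprintf("%02d:00:00", config$sample_hour)),
                   tz = "UTC")
  t1 <- as.POSIXct(paste(config$end, "23:59:59"), tz = "UTC")
  if (config$cadence == "quarterly") {
    anchors <- seq(t0, t1, by = "3 months") + 45 * 86400
    jitter <- with_seed(config$seed + 1000L,
                        sample(-30:30, length(anchors), replace = TRUE))
    ts <- anchors + jitter * 86400
    return(sort(ts[ts >= t0 & ts <= t1]))
  }
  by <- switch(config$cadence,
               "15 min" = "15 min", "1 hour" = "1 hour", "1 day" = "1 day")
  seq(t0, t1, by = by)
}

# deterministic (noise-free, spike-free) signal at given timestamps
syn_signal <- function(config, timestamp, origin) {
  doy <- day_of_year365(timestamp)
  ty <- years_since(timestamp, origin = origin)
  y <- config$mean +
    config$amp1 * cos(2 * pi * (doy - config$dmax1) / 365) +
    config$amp2 * cos(2 * pi * 2 * (doy - config$dmax2) / 365) +
    config$trend * ty
  if (config$diurnal_amp > 0) {
    hour <- as.POSIXlt(timestamp)$hour + as.POSIXlt(timestamp)$min / 60
    y <- y + config$diurnal_amp *
      cos(2 * pi * (hour - config$diurnal_peak_hour) / 24)
  }
  y
}

#' Generate a synthetic series with known ground truth
#'
#' Builds the sampling grid implied by the config, evaluates the deterministic
#' signal (mean + harmonics + trend + diurnal cycle), adds stationary AR(1)
#' noise generated on the sampling grid, injects spikes of
#' `+/- spike_scale * noise_sd` at uniformly random positions, and removes the
#' configured gap windows. The full config, the signal time origin, and the
#' injected spike timestamps are attached as the `ground_truth` attribute so
#' downstream recovery tests can score themselves.
#'
#' @param config a `syn_config`.
#' @return A `sample_series`; spiked samples carry flag `"spike_truth"` in the
#'   ground-truth sidecar (the series itself is unflagged, as a real record
#'   would be). If the record spans less than one full year a
#'   `short_record` attribute is set.
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  ts <- syn_time_grid(config)
  origin <- ts[1]
  y <- syn_signal(config, ts, origin)
  n <- length(ts)
  spike_idx <- integer(0)
  y <- with_seed(config$seed, {
    if (config$noise_sd > 0) {
      e <- stats::rnorm(n, 0, config$noise_sd)
      if (config$ar1_rho != 0) {
        noise <- stats::filter(e, config$ar1_rho, method = "recursive",
                               init = stats::rnorm(1) * config$noise_sd /
                                 sqrt(1 - config$ar1_rho^2))
        y <- y + as.numeric(noise)
      } else {
        y <- y + e
      }
    }
    if (config$spike_rate > 0 && config$noise_sd > 0) {
      n_spk <- round(config$spike_rate * n)
      spike_idx <- sort(sample.int(n, n_spk))
      y[spike_idx] <- y[spike_idx] +
        sample(c(-1, 1), n_spk, replace = TRUE) *
        config$spike_scale * config$noise_sd
    }
    y
  })
  keep <- rep(TRUE, n)
  for (g in config$gap_spec) {
    g0 <- as.POSIXct(paste(as.Date(g[1]), "00:00:00"), tz = "UTC")
    g1 <- as.POSIXct(paste(as.Date(g[2]), "23:59:59"), tz = "UTC")
    keep <- keep & !(ts >= g0 & ts <= g1)
  }
  out <- sample_series(ts[keep], y[keep], site = config$site,
                       variable = config$variable)
  attr(out, "ground_truth") <- list(
    config = config, origin = origin,
    spike_times = ts[spike_idx[keep[spike_idx]]],
    n_spikes_injected = length(spike_idx))
  if (as.numeric(config$end - config$start) < 364) {
    attr(out, "short_record") <- TRUE
    warning("record spans less than one full year; climatology will be partial")
  }
  out
}

#' Generate a coherent multi-variable site suite
#'
#' Produces temperature, salinity, dissolved oxygen and chlorophyll-a series on
#' a shared time base, plus the derived ground-truth AOU. DO is constructed as
#' `o2_saturation(T, S) - AOU_signal + noise`, so the oxygen module can recover
#' the injected AOU seasonal cycle exactly in the noise-free limit.
#' Chlorophyll is generated log-normally: the harmonic config describes
#' log10(chl) and the stored series is `10^x`.
#'
#' @param temp_config,sal_config `syn_config` for temperature and salinity
#'   (must share cadence/start/end).
#' @param aou_config `syn_config` describing the injected AOU signal (mg/L).
#' @param log10chl_config `syn_config` describing log10(chl).
#' @param do_noise_sd extra white noise added to DO (mg/L).
#' @param seed integer master seed (offsets the per-variable config seeds).
#' @return Named list of `sample_series`: `temperature`, `salinity`, `do`,
#'   `chl`, `log10chl`, `aou_truth` (the injected AOU signal series).
#' @export
generate_site_suite <- function(temp_config, sal_config, aou_config,
                                log10chl_config, do_noise_sd = 0, seed = 1L) {
  cfgs <- list(temp_config, sal_config, aou_config, log10chl_config)
  base <- lapply(cfgs, function(cc) c(cc$cadence, as.character(cc$start),
                                      as.character(cc$end)))
  if (length(unique(vapply(base, paste, character(1), collapse = "|"))) != 1) {
    stop("all configs must share cadence, start and end")
  }
  reseed <- function(cc, off) { cc$seed <- as.integer(seed + off); cc }
  temp <- generate_series(reseed(temp_config, 1L))
  sal <- generate_series(reseed(sal_config, 2L))
  aou_sig <- generate_series(reseed(aou_config, 3L))
  lchl <- generate_series(reseed(log10chl_config, 4L))
  do_val <- o2_saturation(temp$value, sal$value) - aou_sig$value
  if (do_noise_sd > 0) {
    do_val <- do_val + with_seed(as.integer(seed + 5L),
                                 stats::rnorm(length(do_val), 0, do_noise_sd))
  }
  do_series <- sample_series(temp$timestamp, do_val,
                             site = attr(temp, "site"), variable = "do")
  chl <- sample_series(lchl$timestamp, 10^lchl$value,
                       site = attr(lchl, "site"), variable = "chl")
  aou_truth <- sample_series(aou_sig$timestamp, aou_sig$value,
                             site = attr(aou_sig, "site"), variable = "aou")
  lchl2 <- sample_series(lchl$timestamp, lchl$value,
                         site = attr(lchl, "site"), variable = "log10chl")
  list(temperature = temp, salinity = sal, do = do_series, chl = chl,
       log10chl = lchl2, aou_truth = aou_truth)
}
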