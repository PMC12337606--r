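#' Reference harmonic fit of a dense daily series
#'
#' Fits the composite harmonic model to a daily-averaged high-frequency record
#' and returns everything subsampling trials are scored against: the fit, the
#' composite extrema, bootstrap confidence intervals on all elements, and the
#' standard deviation of the deseasonalized anomalies (the nRMSE normalizer).
#'
#' @param daily_series a daily-averaged `sample_series` spanning >= 2 years.
#' @param n_boot bootstrap resamples for the reference CIs.
#' @param seed seed for the bootstrap.
#' @param K number of harmonics.
#' @return A `reference_fit` list: `fit`, `summary`, `ci` (`bootstrap_ci`),
#'   `anomaly_sd` (NA with `degenerate = TRUE` when the record is noise-free),
#'   `clim`.
#' @export
reference_fit <- function(daily_series, n_boot = 1000, seed = NULL, K = 2) {
  span <- as.numeric(diff(range(daily_series$timestamp)), units = "days")
  if (span < 2 * 365) stop("reference fit needs >= 2 years of daily data")
  clim <- to_climatology(daily_series)
  fit <- fit_harmonics(clim, K = K)
  anom <- daily_series$value - predict(fit, clim$doy)
  asd <- stats::sd(anom)
  degenerate <- asd < 1e-12
  structure(list(fit = fit, summary = composite_extrema(fit),
                 ci = bootstrap_fit(clim, n_boot = n_boot, seed = seed, K = K),
                 anomaly_sd = if (degenerate) NA_real_ else asd,
                 degenerate = degenerate, clim = clim),
            class = "reference_fit")
}

#' RMSE between two fitted seasonal curves
#'
#' Curves are evaluated on the 365 integer year-days; the squared differences
#' are summed and divided by `nu`, the number of subsampled values in the
#' trial, used as the degrees-of-freedom estimate.
#'
#' @param reference_curve,trial_curve numeric vectors of length 365 (or
#'   `harmonic_fit` objects, evaluated internally).
#' @param nu degrees of freedom (trial sample count).
#' @return RMSE in variable units.
#' @export
rmse_fit <- function(reference_curve, trial_curve, nu) {
  if (inherits(reference_curve, "harmonic_fit")) {
    reference_curve <- predict(reference_curve, 1:365)
  }
  if (inherits(trial_curve, "harmonic_fit")) {
    trial_curve <- predict(trial_curve, 1:365)
  }
  if (length(reference_curve) != 365 || length(trial_curve) != 365) {
    stop("curves must be evaluated on the 365 integer year-days")
  }
  sqrt(sum((reference_curve - trial_curve)^2) / nu)
}

#' Normalized RMSE
#'
#' RMSE divided by the SD of the deseasonalized anomalies of the reference
#' record. Undefined (NA, with a warning) when the reference is noise-free.
#'
#' @param rmse RMSE from [rmse_fit]. @param anomaly_sd the normalizer.
#' @return Dimensionless nRMSE.
#' @export
nrmse <- function(rmse, anomaly_sd) {
  if (is.na(anomaly_sd) || anomaly_sd == 0) {
    warning("anomaly SD is zero; nRMSE undefined")
    return(NA_real_)
  }
  rmse / anomaly_sd
}

#' Nash-Sutcliffe efficiency of a subsampling trial
#'
#' `NSE = 1 - (RMSE / sd_trial)^2`, where `sd_trial` is the standard deviation
#' of the randomly subsampled values of the trial. NSE = 1 means no error;
#' NSE = 0 means the error variance matches the observed variance. Skill
#' classes: >= 0.90 very good, 0.80-0.90 good, 0.65-0.80 acceptable,
#' < 0.65 unsatisfactory.
#'
#' @param rmse trial RMSE. @param sd_trial SD of the trial's sampled values.
#' @return List with `nse` and `class`.
#' @export
nse <- function(rmse, sd_trial) {
  val <- 1 - (rmse / sd_trial)^2
  list(nse = val, class = nse_class(val))
}

#' @rdname nse
#' @param nse_value a numeric NSE.
#' @export
nse_class <- function(nse_value) {
  ifelse(nse_value >= 0.90, "very good",
         ifelse(nse_value >= 0.80, "good",
                ifelse(nse_value >= 0.65, "acceptable", "unsatisfactory")))
}

# one trial: fit harmonics to sampled rows of the reference climatology
subsample_trial <- function(ref, idx, K) {
  cl <- ref$clim[idx, , drop = FALSE]
  fit <- tryCatch(fit_harmonics(cl, K = K), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  rm <- rmse_fit(predict(ref$fit, 1:365), predict(fit, 1:365),
                 nu = length(idx))
  sd_trial <- stats::sd(cl$value)
  list(fit = fit, elements = fit_element_vector(fit),
       rmse = rm,
       nrmse = if (ref$degenerate) NA_real_ else rm / ref$anomaly_sd,
       nse = 1 - (rm / sd_trial)^2, n = length(idx))
}

#' Density-matched subsampling experiment
#'
#' Draws sparse records from a dense daily reference at the sampling density
#' of a low-frequency monitoring program: within each calendar quarter
#' (Jan-Mar, Apr-Jun, Jul-Sep, Oct-Dec; all years pooled) the stated number of
#' days is drawn uniformly without replacement. Each trial is refit and scored
#' against the reference curve with RMSE, nRMSE and NSE.
#'
#' @param daily_series dense daily `sample_series` (or a `reference_fit`).
#' @param counts_per_quarter integer vector of length 4 (recycled from length
#'   1): days drawn per quarter.
#' @param n_trials number of trials (default 200).
#' @param seed integer seed for the whole experiment.
#' @param K number of harmonics.
#' @return A `subsample_experiment` list: `trials` (per-trial element vectors
#'   and scores), `reference`, `mean_nrmse`, `mean_nse`, `nse_class`.
#' @export
subsample_density <- function(daily_series, counts_per_quarter,
                              n_trials = 200, seed = NULL, K = 2) {
  ref <- if (inherits(daily_series, "reference_fit")) daily_series else
    reference_fit(daily_series, seed = seed)
  counts <- rep(as.integer(counts_per_quarter), length.out = 4)
  qtr <- calendar_quarter(ref$clim$timestamp)
  pools <- split(seq_len(nrow(ref$clim)), qtr)
  avail <- vapply(pools, length, integer(1))
  if (any(counts > avail)) {
    stop(sprintf("requested %d samples in quarter %d but only %d available",
                 counts[which.max(counts / avail)],
                 which.max(counts / avail), min(avail)))
  }
  trials <- with_seed(seed, {
    lapply(seq_len(n_trials), function(b) {
      idx <- unlist(lapply(1:4, function(q) {
        if (counts[q] == length(pools[[q]])) pools[[q]] else
          sample(pools[[q]], counts[q])
      }))
      subsample_trial(ref, idx, K)
    })
  })
  trials <- Filter(Negate(is.null), trials)
  nse_vals <- vapply(trials, `[[`, numeric(1), "nse")
  structure(list(trials = trials, reference = ref,
                 counts_per_quarter = counts, n_trials = length(trials),
                 mean_rmse = mean(vapply(trials, `[[`, numeric(1), "rmse")),
                 mean_nrmse = mean(vapply(trials, `[[`, numeric(1), "nrmse")),
                 mean_nse = mean(nse_vals),
                 nse_class = nse_class(mean(nse_vals)),
                 seed = seed),
            class = "subsample_experiment")
}

#' Sampling-duration sweep
#'
#' For each candidate duration `N` years of quarterly sampling, draws `N`
#' days per season (4 N samples per simulated record) from the pooled
#' day-of-year record, fits the harmonic model, and aggregates the harmonic
#' elements over `n_trials` trials: their mean, SD, normalized SD (nSD, SD
#' over its large-N asymptote taken as the mean SD across the upper half of
#' the N grid), and the mean nRMSE. Draws are without replacement within a
#' trial whenever the pooled quarter holds enough days, otherwise with
#' replacement across the pool (the climatological-pooling regime needed when
#' the sweep extends past the reference record length).
#'
#' @param daily_series dense daily `sample_series` (or a `reference_fit`).
#' @param n_yrs_grid strictly increasing integer durations (default
#'   `c(5, 10, 15, 20, 25, 30, 40, 50)`).
#' @param n_trials trials per grid value (default 200).
#' @param seed integer seed. @param K number of harmonics.
#' @return A `duration_curve` list: `table` (per-N element means/SDs/nSD and
#'   mean nRMSE, long format), `n_yrs_grid`, `n_trials`, `reference`.
#' @export
sweep_duration <- function(daily_series,
                           n_yrs_grid = c(5, 10, 15, 20, 25, 30, 40, 50),
                           n_trials = 200, seed = NULL, K = 2) {
  if (is.unsorted(n_yrs_grid, strictly = TRUE)) {
    stop("n_yrs_grid must be strictly increasing")
  }
  ref <- if (inherits(daily_series, "reference_fit")) daily_series else
    reference_fit(daily_series, seed = seed)
  qtr <- calendar_quarter(ref$clim$timestamp)
  pools <- split(seq_len(nrow(ref$clim)), qtr)
  res <- with_seed(seed, {
    lapply(n_yrs_grid, function(N) {
      per_trial <- lapply(seq_len(n_trials), function(b) {
        idx <- unlist(lapply(pools, function(p) {
          if (N <= length(p)) sample(p, N) else sample(p, N, replace = TRUE)
        }))
        subsample_trial(ref, idx, K)
      })
      per_trial <- Filter(Negate(is.null), per_trial)
      if (length(per_trial) == 0) {
        stop(sprintf(paste0("no trial at N = %d years could be fit; ",
                            "4N samples must exceed the %d model parameters"),
                     N, 2 * K + 1))
      }
      el <- do.call(rbind, lapply(per_trial, `[[`, "elements"))
      # circular SD/mean for date elements: unwrap around reference value
      refel <- fit_element_vector(ref$fit)
      for (j in which(is_date_element(colnames(el)))) {
        per <- if (grepl("_2$", colnames(el)[j])) 365 / 2 else 365
        el[, j] <- refel[j] + circ_day_diff(el[, j], refel[j], period = per)
      }
      list(N = N,
           mean = colMeans(el), sd = apply(el, 2, stats::sd),
           mean_nrmse = mean(vapply(per_trial, `[[`, numeric(1), "nrmse")),
           n_trials = length(per_trial))
    })
  })
  elements <- names(res[[1]]$mean)
  sd_mat <- do.call(rbind, lapply(res, `[[`, "sd"))
  upper <- n_yrs_grid >= stats::median(n_yrs_grid)
  asymptote <- colMeans(sd_mat[upper, , drop = FALSE])
  tab <- do.call(rbind, lapply(seq_along(res), function(i) {
    data.frame(n_yrs = res[[i]]$N, element = elements,
               mean = unname(res[[i]]$mean), sd = unname(res[[i]]$sd),
               nsd = unname(res[[i]]$sd / asymptote[elements]),
               mean_nrmse = res[[i]]$mean_nrmse,
               row.names = NULL)
  }))
  structure(list(table = tab, n_yrs_grid = n_yrs_grid,
                 n_trials = n_trials, reference = ref,
                 sd_asymptote = asymptote, seed = seed),
            class = "duration_curve")
}

#' Normalized SD of one harmonic element along the duration sweep
#'
#' @param curve a `duration_curve`. @param element element name (e.g. `"C_1"`,
#'   `"composite_amplitude"`, `"date_of_max"`).
#' @return Data frame `n_yrs`, `nsd`.
#' @export
nsd <- function(curve, element) {
  tab <- curve$table[curve$table$element == element, ]
  data.frame(n_yrs = tab$n_yrs, nsd = tab$nsd)
}

#' Minimum sampling duration per harmonic element
#'
#' The minimum duration for an element is the smallest grid value `N` at which
#' the trial-mean element at `N` and at the next grid value both fall inside
#' the reference bootstrap confidence interval. When no `N` qualifies, the
#' grid value whose trial mean is closest to the CI midpoint is returned with
#' `attained = FALSE` and a note.
#'
#' @param curve a `duration_curve`.
#' @param reference_ci a `bootstrap_ci` for the reference record (defaults to
#'   the one inside `curve$reference`).
#' @param elements which elements to assess (default: all shared ones).
#' @return Data frame: `element`, `n_min`, `attained`, `note`.
#' @export
minimum_duration <- function(curve, reference_ci = NULL, elements = NULL) {
  if (is.null(reference_ci)) reference_ci <- curve$reference$ci
  tab <- curve$table
  if (is.null(elements)) {
    elements <- intersect(unique(tab$element), rownames(reference_ci$ci))
  }
  grid <- curve$n_yrs_grid
  rows <- lapply(elements, function(el) {
    m <- tab$mean[tab$element == el][order(tab$n_yrs[tab$element == el])]
    lo <- reference_ci$ci[el, "lower"]; hi <- reference_ci$ci[el, "upper"]
    inside <- m >= lo & m <= hi
    ok <- which(inside[-length(inside)] & inside[-1])
    if (length(ok) > 0) {
      data.frame(element = el, n_min = grid[ok[1]], attained = TRUE,
                 note = "")
    } else {
      mid <- (lo + hi) / 2
      data.frame(element = el, n_min = grid[which.min(abs(m - mid))],
                 attained = FALSE,
                 note = "never inside reference CI; closest value selected")
    }
  })
  do.call(rbind, rows)
}
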