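#' Compile a series into a climatological day-of-year record
#'
#' Pools all observations onto day of year 1..365 (see [day_of_year365] for
#' the leap-day convention). Source timestamps are retained so anomalies can
#' be mapped back to calendar time.
#'
#' @param series a `sample_series`.
#' @return A `climatology_series` data frame with columns `doy`, `value`,
#'   `timestamp`.
#' @export
to_climatology <- function(series) {
  if (nrow(series) == 0) stop("empty series")
  out <- data.frame(doy = day_of_year365(series$timestamp),
                    value = series$value,
                    timestamp = series$timestamp)
  span <- diff(range(series$timestamp))
  structure(out, class = c("climatology_series", "data.frame"),
            site = attr(series, "site"), variable = attr(series, "variable"),
            units = attr(series, "units"),
            full_year = as.numeric(span, units = "days") >= 364)
}

# design matrix of the K-harmonic model on day-of-year t
harmonic_design <- function(t, K) {
  X <- matrix(1, length(t), 2 * K + 1)
  for (k in seq_len(K)) {
    w <- 2 * pi * k * t / 365
    X[, 2 * k] <- cos(w)
    X[, 2 * k + 1] <- sin(w)
  }
  X
}

# amplitude/phase/date-of-max elements from raw OLS coefficients
harmonic_elements <- function(coef, K) {
  a <- coef[2 * seq_len(K)]
  b <- coef[2 * seq_len(K) + 1]
  amp <- sqrt(a^2 + b^2)
  phase <- atan2(b, a)
  dmax <- (365 / (2 * pi * seq_len(K))) * phase
  period <- 365 / seq_len(K)
  dmax <- dmax %% period
  dmax[dmax == 0] <- period[dmax == 0]   # report in (0, 365/k]
  list(mean = unname(coef[1]), cos_coef = unname(a), sin_coef = unname(b),
       amplitude = unname(amp), phase = unname(phase),
       date_of_max = unname(dmax))
}

#' Fit annual and semi-annual harmonics to a climatological record
#'
#' Ordinary least squares of the observed values on the constant plus
#' `cos(2*pi*k*t/365)` and `sin(2*pi*k*t/365)` for harmonics `k = 1..K`,
#' where `t` is day of year. For each harmonic the amplitude
#' `C_k = sqrt(a_k^2 + b_k^2)`, phase `atan2(b_k, a_k)` and date of maximum
#' are derived, along with the variance fraction each harmonic explains
#' (a sinusoid of amplitude C contributes variance C^2/2), the residual SD,
#' and a reduced chi-squared computed against the residual SD (so ~1 unless a
#' measurement sigma is supplied to [reduced_chi_squared]).
#'
#' @param clim a `climatology_series` (or `sample_series`, converted
#'   internally).
#' @param K number of harmonics (default 2: annual + semi-annual).
#' @return A `harmonic_fit` object.
#' @export
fit_harmonics <- function(clim, K = 2) {
  if (inherits(clim, "sample_series")) clim <- to_climatology(clim)
  if (length(unique(clim$doy)) < 2 * K + 1) {
    stop(sprintf("need >= %d distinct days of year to fit %d harmonics",
                 2 * K + 1, K))
  }
  X <- harmonic_design(clim$doy, K)
  fit <- stats::lm.fit(X, clim$value)
  if (fit$rank < ncol(X)) stop("rank-deficient harmonic design")
  el <- harmonic_elements(fit$coefficients, K)
  n <- nrow(clim)
  dof <- n - (2 * K + 1)
  resid_sd <- if (dof > 0) sqrt(sum(fit$residuals^2) / dof) else NA_real_
  tot_var <- stats::var(clim$value)
  var_frac <- if (isTRUE(tot_var > 0)) (el$amplitude^2 / 2) / tot_var else
    rep(NA_real_, K)
  fitted_var <- sum(el$amplitude^2 / 2)
  fitted_frac <- if (fitted_var > 0) (el$amplitude^2 / 2) / fitted_var else
    rep(NA_real_, K)
  structure(list(
    K = K, mean = el$mean, cos_coef = el$cos_coef, sin_coef = el$sin_coef,
    amplitude = el$amplitude, phase = el$phase, date_of_max = el$date_of_max,
    var_fraction = var_frac,            # share of total sample variance
    fitted_var_fraction = fitted_frac,  # share of total fitted variance
    total_var_captured = sum(var_frac),
    dominant_harmonic = which.max(el$amplitude),
    resid_sd = resid_sd,
    red_chisq = if (is.na(resid_sd) || resid_sd == 0) NA_real_ else 1,
    n_obs = n),
    class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("<harmonic_fit> K=%d n=%d mean=%.4g resid_sd=%.4g\n",
              x$K, x$n_obs, x$mean, x$resid_sd))
  for (k in seq_len(x$K)) {
    cat(sprintf("  k=%d: C=%.4g date_of_max=%.2f var_fraction=%.3f\n",
                k, x$amplitude[k], x$date_of_max[k], x$var_fraction[k]))
  }
  invisible(x)
}

#' Evaluate the fitted composite harmonic curve
#'
#' @param object a `harmonic_fit`. @param t day of year (may be fractional).
#' @param ... unused.
#' @return Fitted values of the composite (mean + all harmonics) curve.
#' @export
predict.harmonic_fit <- function(object, t, ...) {
  y <- rep(object$mean, length(t))
  for (k in seq_len(object$K)) {
    w <- 2 * pi * k * t / 365
    y <- y + object$cos_coef[k] * cos(w) + object$sin_coef[k] * sin(w)
  }
  y
}

#' Variance fractions per harmonic
#'
#' `fraction_k = (C_k^2 / 2) / var(y)`; also reports fractions of the total
#' fitted variance (which sum to 1) and the dominant harmonic. The dominant
#' harmonic is invariant to which denominator is used.
#'
#' @param fit a `harmonic_fit`. @param clim the climatology it was fit to.
#' @return List with `of_total`, `of_fitted`, `total_captured`, `dominant`.
#' @export
variance_fractions <- function(fit, clim) {
  if (inherits(clim, "sample_series")) clim <- to_climatology(clim)
  tot <- stats::var(clim$value)
  of_total <- if (isTRUE(tot > 0)) (fit$amplitude^2 / 2) / tot else
    rep(NA_real_, fit$K)
  list(of_total = of_total, of_fitted = fit$fitted_var_fraction,
       total_captured = sum(of_total), dominant = fit$dominant_harmonic)
}

#' Extrema of the composite seasonal curve
#'
#' Locates the zero-points of the first time derivative of the composite
#' harmonic curve on (0, 365]: a sign-change scan on a fine grid (step
#' `grid_step`, default 0.01 d) refined by bisection to |dt| < 1e-6 d. The
#' composite seasonal amplitude is half the max-minus-min range. Ties between
#' equal extrema (within 1e-9 of the extreme value) report the earliest date
#' and set `multiple_max` / `multiple_min`.
#'
#' @param fit a `harmonic_fit` with K >= 1.
#' @param grid_step scan step in days (<= 0.01 recommended).
#' @return A `composite_summary` list: `date_of_max`, `date_of_min`,
#'   `value_at_max`, `value_at_min`, `composite_amplitude`, `flat`,
#'   `multiple_max`, `multiple_min`.
#' @export
composite_extrema <- function(fit, grid_step = 0.01) {
  if (all(fit$amplitude < 1e-12)) {
    return(structure(list(date_of_max = NA_real_, date_of_min = NA_real_,
                          value_at_max = fit$mean, value_at_min = fit$mean,
                          composite_amplitude = 0, flat = TRUE,
                          multiple_max = FALSE, multiple_min = FALSE),
                     class = "composite_summary"))
  }
  deriv <- function(t) {
    d <- 0
    for (k in seq_len(fit$K)) {
      w <- 2 * pi * k / 365
      d <- d + w * (-fit$cos_coef[k] * sin(w * t) +
                      fit$sin_coef[k] * cos(w * t))
    }
    d
  }
  tg <- seq(0, 365, by = grid_step)
  dg <- deriv(tg)
  sgn <- sign(dg)
  # walk past exact zeros when detecting sign changes
  flip <- which(sgn[-length(sgn)] * sgn[-1] < 0 | dg[-length(dg)] == 0)
  roots <- vapply(flip, function(i) {
    if (dg[i] == 0) return(tg[i])
    stats::uniroot(deriv, c(tg[i], tg[i + 1]), tol = 1e-7)$root
  }, numeric(1))
  roots <- roots[roots > 0 & roots <= 365]
  roots <- sort(unique(round(roots, 6)))
  vals <- predict(fit, roots)
  vmax <- max(vals); vmin <- min(vals)
  at_max <- which(vals >= vmax - 1e-9)
  at_min <- which(vals <= vmin + 1e-9)
  structure(list(date_of_max = roots[at_max[1]],
                 date_of_min = roots[at_min[1]],
                 value_at_max = vmax, value_at_min = vmin,
                 composite_amplitude = (vmax - vmin) / 2,
                 flat = FALSE,
                 multiple_max = length(at_max) > 1,
                 multiple_min = length(at_min) > 1),
            class = "composite_summary")
}

#' @export
print.composite_summary <- function(x, ...) {
  cat(sprintf(paste0("<composite_summary> max %.4g @ day %.2f, ",
                     "min %.4g @ day %.2f, amplitude %.4g\n"),
              x$value_at_max, x$date_of_max, x$value_at_min, x$date_of_min,
              x$composite_amplitude))
  invisible(x)
}

# all scalar elements of a fit (+ composite summary) as a named vector
fit_element_vector <- function(fit, composite = TRUE) {
  el <- c(mean = fit$mean)
  for (k in seq_len(fit$K)) {
    el[[paste0("C_", k)]] <- fit$amplitude[k]
    el[[paste0("date_of_max_", k)]] <- fit$date_of_max[k]
  }
  if (composite) {
    cs <- composite_extrema(fit)
    el[["composite_amplitude"]] <- cs$composite_amplitude
    el[["date_of_max"]] <- cs$date_of_max
    el[["date_of_min"]] <- cs$date_of_min
    el[["value_at_max"]] <- cs$value_at_max
    el[["value_at_min"]] <- cs$value_at_min
  }
  el
}

# which elements are circular day-of-year dates
is_date_element <- function(names) grepl("^date_of", names)

#' Case-resampling bootstrap confidence intervals for harmonic elements
#'
#' Observations are resampled with replacement, the harmonic model refit, and
#' all elements (mean, per-harmonic amplitudes and dates of maximum, and
#' optionally the composite extrema) recomputed. Percentile intervals are
#' reported. Date elements are circular: each resampled date is unwrapped onto
#' the real line around the point estimate before taking percentiles. Case
#' resampling (rather than residual resampling) is used because seasonal
#' heteroscedasticity is the norm in these records.
#'
#' @param clim a `climatology_series` (or `sample_series`).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for reproducible resampling.
#' @param K number of harmonics. @param composite include composite extrema
#'   elements (slower)?
#' @return A `bootstrap_ci` object: matrix `ci` (rows = elements, columns
#'   `lower`, `point`, `upper`), `n_boot`, `level`, `seed`, and the matrix of
#'   bootstrap replicates.
#' @export
bootstrap_fit <- function(clim, n_boot = 1000, level = 0.95, seed = NULL,
                          K = 2, composite = TRUE) {
  if (inherits(clim, "sample_series")) clim <- to_climatology(clim)
  n <- nrow(clim)
  if (n < 20) stop("bootstrap needs >= 20 observations")
  point_fit <- fit_harmonics(clim, K = K)
  point <- fit_element_vector(point_fit, composite = composite)
  X <- harmonic_design(clim$doy, K)
  y <- clim$value
  reps <- with_seed(seed, {
    out <- matrix(NA_real_, n_boot, length(point),
                  dimnames = list(NULL, names(point)))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      cf <- stats::lm.fit(X[idx, , drop = FALSE], y[idx])$coefficients
      if (anyNA(cf)) next
      el <- harmonic_elements(cf, K)
      v <- c(mean = el$mean)
      for (k in seq_len(K)) {
        v[[paste0("C_", k)]] <- el$amplitude[k]
        v[[paste0("date_of_max_", k)]] <- el$date_of_max[k]
      }
      if (composite) {
        bf <- list(K = K, mean = el$mean, cos_coef = el$cos_coef,
                   sin_coef = el$sin_coef, amplitude = el$amplitude)
        cs <- composite_extrema(structure(bf, class = "harmonic_fit"))
        v[["composite_amplitude"]] <- cs$composite_amplitude
        v[["date_of_max"]] <- cs$date_of_max
        v[["date_of_min"]] <- cs$date_of_min
        v[["value_at_max"]] <- cs$value_at_max
        v[["value_at_min"]] <- cs$value_at_min
      }
      out[b, ] <- v
    }
    out
  })
  # unwrap circular date elements around the point estimate
  for (j in which(is_date_element(colnames(reps)))) {
    k <- if (grepl("_2$", colnames(reps)[j])) 2 else 1
    per <- 365 / k
    reps[, j] <- point[j] + circ_day_diff(reps[, j], point[j], period = per)
  }
  alpha <- (1 - level) / 2
  qs <- apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  ci <- cbind(lower = qs[1, ], point = point, upper = qs[2, ])
  structure(list(ci = ci, n_boot = n_boot, level = level, seed = seed,
                 replicates = reps),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> %d resamples, %.0f%% percentile intervals\n",
              x$n_boot, 100 * x$level))
  print(round(x$ci, 4))
  invisible(x)
}

#' Reduced chi-squared of a harmonic fit
#'
#' `sum(((y - yhat) / sigma)^2) / (n - (2K + 1))`. When `sigma` is omitted the
#' residual SD of the fit is used, which makes the statistic ~1 by
#' construction; supply an independent measurement sigma to test goodness of
#' fit.
#'
#' @param fit a `harmonic_fit`. @param clim the climatology it was fit to.
#' @param sigma per-observation SD (scalar or vector); default residual SD.
#' @return Dimensionless reduced chi-squared.
#' @export
reduced_chi_squared <- function(fit, clim, sigma = NULL) {
  if (inherits(clim, "sample_series")) clim <- to_climatology(clim)
  resid <- clim$value - predict(fit, clim$doy)
  if (is.null(sigma)) sigma <- fit$resid_sd
  dof <- nrow(clim) - (2 * fit$K + 1)
  sum((resid / sigma)^2) / dof
}

#' Deseasonalized anomalies
#'
#' Subtracts the fitted climatological value at each observation's day of year,
#' preserving timestamps. Anomalies carry interannual variability and any
#' long-term trend.
#'
#' @param series a `sample_series`. @param fit a `harmonic_fit` for the same
#'   variable.
#' @return A `sample_series` of anomalies.
#' @export
deseasonalize <- function(series, fit) {
  doy <- day_of_year365(series$timestamp)
  sample_series(series$timestamp, series$value - predict(fit, doy),
                site = attr(series, "site"),
                variable = paste0(attr(series, "variable"), "_anomaly"),
                units = attr(series, "units"), flag = series$flag)
}
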