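#' Generalized-least-squares trend on deseasonalized anomalies
#'
#' Fits `anomaly = b0 + b1 * t_years` with AR(1) error covariance by two-stage
#' feasible GLS: an OLS first pass, the AR(1) parameter estimated as the lag-1
#' autocorrelation of the OLS residuals taken in observation order, then one
#' GLS refit under that covariance (a Prais-Winsten transform). Time is
#' measured in continuous years from the first observation, so the slope is in
#' variable units per year. The two-sided p-value for slope = 0 uses the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param anomalies a `sample_series` of deseasonalized anomalies spanning
#'   >= 3 years with >= 12 observations.
#' @param alpha significance threshold for the reported flag (default 0.05).
#' @return A `trend_result`: `slope`, `slope_se`, `p_value`, `ar1_rho_hat`,
#'   `n_obs`, `span_years`, `significant`, `intercept`.
#' @export
gls_trend <- function(anomalies, alpha = 0.05) {
  y <- anomalies$value
  t <- years_since(anomalies$timestamp)
  n <- length(y)
  span <- max(t) - min(t)
  if (span < 3) stop("trend estimation needs >= 3 years of data")
  if (n < 12) stop("trend estimation needs >= 12 observations")
  if (stats::sd(t) == 0) stop("degenerate time design: all observations at one time")
  # stage 1: OLS and residual lag-1 autocorrelation in observation order
  X <- cbind(1, t)
  ols <- stats::lm.fit(X, y)
  r <- ols$residuals
  rho <- sum(r[-1] * r[-n]) / sum(r^2)
  rho <- max(min(rho, 0.99), -0.99)
  # stage 2: Prais-Winsten transform and GLS refit
  ys <- c(sqrt(1 - rho^2) * y[1], y[-1] - rho * y[-n])
  Xs <- rbind(sqrt(1 - rho^2) * X[1, ], X[-1, ] - rho * X[-n, ])
  gls <- stats::lm.fit(Xs, ys)
  rss <- sum(gls$residuals^2)
  sigma2 <- rss / (n - 2)
  XtXinv <- chol2inv(chol(crossprod(Xs)))
  se <- sqrt(sigma2 * diag(XtXinv))
  tstat <- gls$coefficients[2] / se[2]
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(slope = unname(gls$coefficients[2]),
                 slope_se = unname(se[2]),
                 p_value = unname(p),
                 ar1_rho_hat = rho,
                 n_obs = n, span_years = span,
                 significant = unname(p < alpha),
                 intercept = unname(gls$coefficients[1])),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "<trend_result> slope=%.4g +/- %.4g per yr, p=%.3g, rho=%.3f, n=%d (%.1f yr)\n",
    x$slope, x$slope_se, x$p_value, x$ar1_rho_hat, x$n_obs, x$span_years))
  invisible(x)
}

#' Pool trend slopes across sites
#'
#' Arithmetic mean of site slopes with the standard error propagated under
#' independence of the per-site regression errors:
#' `SE = sqrt(sum(se_i^2)) / m`.
#'
#' @param site_trends list of `trend_result` objects (or numeric slopes with a
#'   matching `ses` vector).
#' @param ses per-site slope SEs when `site_trends` is numeric.
#' @return List with `mean_slope`, `se`, `m`.
#' @export
pool_trends <- function(site_trends, ses = NULL) {
  if (is.list(site_trends) && inherits(site_trends[[1]], "trend_result")) {
    slopes <- vapply(site_trends, `[[`, numeric(1), "slope")
    ses <- vapply(site_trends, `[[`, numeric(1), "slope_se")
  } else {
    slopes <- as.numeric(site_trends)
    if (is.null(ses)) stop("supply per-site SEs")
  }
  m <- length(slopes)
  list(mean_slope = mean(slopes), se = sqrt(sum(ses^2)) / m, m = m)
}

#' Seasonal-cycle shifts between record halves
#'
#' Splits a record at its temporal midpoint, fits the harmonic model and
#' composite extrema to each half, and reports late-minus-early differences of
#' every harmonic element. Date differences are circular, reported in
#' (-182.5, 182.5] days (and (-91.25, 91.25] for the semi-annual date).
#'
#' @param series a `sample_series` spanning >= 10 years.
#' @param K number of harmonics.
#' @return A `split_half_result`: `fit_early`, `fit_late`, `summary_early`,
#'   `summary_late`, and `deltas` (named numeric vector).
#' @export
split_half_shift <- function(series, K = 2) {
  span <- as.numeric(diff(range(series$timestamp)), units = "days") / 365.25
  if (span < 10) stop("split-half analysis needs >= 10 years of data")
  mid <- min(series$timestamp) + diff(range(series$timestamp)) / 2
  early <- series_like(series, series[series$timestamp < mid, , drop = FALSE])
  late <- series_like(series, series[series$timestamp >= mid, , drop = FALSE])
  fits <- lapply(list(early = early, late = late), function(h) {
    which_half <- if (identical(h$timestamp, early$timestamp)) "early" else "late"
    cl <- to_climatology(h)
    if (length(unique(cl$doy)) < 2 * K + 1) {
      stop(sprintf("insufficient seasonal coverage in %s half", which_half))
    }
    fit_harmonics(cl, K = K)
  })
  el_early <- fit_element_vector(fits$early)
  el_late <- fit_element_vector(fits$late)
  deltas <- el_late - el_early
  for (j in which(is_date_element(names(deltas)))) {
    per <- if (grepl("_2$", names(deltas)[j])) 365 / 2 else 365
    deltas[j] <- circ_day_diff(el_late[j], el_early[j], period = per)
  }
  structure(list(fit_early = fits$early, fit_late = fits$late,
                 summary_early = composite_extrema(fits$early),
                 summary_late = composite_extrema(fits$late),
                 deltas = deltas),
            class = "split_half_result")
}

#' @export
print.split_half_result <- function(x, ...) {
  cat("<split_half_result> late - early deltas:\n")
  print(round(x$deltas, 4))
  invisible(x)
}

#' Group comparison of split-half deltas
#'
#' Welch two-sample t-tests comparing the mean of each element's delta between
#' two groups of sites (e.g. mainland vs ocean-inlet).
#'
#' @param results list of `split_half_result`, one per site.
#' @param group factor/character of length `length(results)` with two levels.
#' @return Data frame: element, mean per group, t statistic, p value.
#' @export
split_half_ttests <- function(results, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two site groups required")
  d <- do.call(rbind, lapply(results, `[[`, "deltas"))
  g1 <- levels(group)[1]; g2 <- levels(group)[2]
  rows <- lapply(colnames(d), function(el) {
    tt <- stats::t.test(d[group == g1, el], d[group == g2, el])
    data.frame(element = el,
               mean_group1 = mean(d[group == g1, el]),
               mean_group2 = mean(d[group == g2, el]),
               t_stat = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- c(g1, g2)
  out
}

#' Trend table across sites and variables
#'
#' Convenience formatter mirroring a site-by-variable trend report.
#'
#' @param trends named list of `trend_result` (names like "site.variable" or
#'   arbitrary labels).
#' @return Data frame with slope, SE, p value, and significance flag at 0.05.
#' @export
trend_table <- function(trends) {
  do.call(rbind, lapply(names(trends), function(nm) {
    tr <- trends[[nm]]
    data.frame(label = nm, slope = tr$slope, se = tr$slope_se,
               p_value = tr$p_value, significant = tr$significant)
  }))
}
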