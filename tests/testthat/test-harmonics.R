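test_that("day-of-year convention handles leap years", {
  expect_equal(day_of_year365(as.POSIXct("2021-01-01", tz = "UTC")), 1L)
  expect_equal(day_of_year365(as.POSIXct("2020-02-29", tz = "UTC")), 60L)
  expect_equal(day_of_year365(as.POSIXct("2020-03-01", tz = "UTC")), 60L)
  expect_equal(day_of_year365(as.POSIXct("2020-12-31", tz = "UTC")), 365L)
  expect_equal(day_of_year365(as.POSIXct("2021-03-01", tz = "UTC")), 60L)
  expect_equal(day_of_year365(as.POSIXct("2021-12-31", tz = "UTC")), 365L)
})

test_that("ten years of daily data cover every day of year", {
  s <- noisy_daily(years = 10, noise_sd = 0)
  cl <- to_climatology(s)
  expect_equal(nrow(cl), nrow(s))
  expect_setequal(unique(cl$doy), 1:365)
})

test_that("noise-free harmonics are recovered exactly", {
  s <- noisefree_year(mean = 10, amp1 = 5, dmax1 = 200)
  fit <- fit_harmonics(to_climatology(s))
  expect_equal(fit$mean, 10, tolerance = 1e-10)
  expect_equal(fit$amplitude[1], 5, tolerance = 1e-10)
  expect_equal(fit$date_of_max[1], 200, tolerance = 1e-8)
  expect_lt(fit$amplitude[2], 1e-10)
})

test_that("a constant series fits to its constant with zero amplitudes", {
  ts <- as.POSIXct("2015-01-01", tz = "UTC") + 0:364 * 86400
  fit <- fit_harmonics(to_climatology(sample_series(ts, rep(3.7, 365))))
  expect_equal(fit$mean, 3.7)
  expect_lt(max(fit$amplitude), 1e-12)
})

test_that("noisy amplitude recovery stays within its analytic SE band", {
  # SE of a sinusoid amplitude from N noisy points is sigma * sqrt(2 / N)
  amps <- vapply(1:200, function(seed) {
    fit_harmonics(to_climatology(noisy_daily(years = 10, noise_sd = 1,
                                             seed = seed)))$amplitude[1]
  }, numeric(1))
  expect_equal(mean(amps), 5, tolerance = 0.02)
  se <- 1 * sqrt(2 / 3650)
  expect_equal(sd(amps), se, tolerance = 0.25)
})

test_that("variance fractions follow C^2/2 proportions", {
  s1 <- noisefree_year(mean = 0, amp1 = 4, amp2 = 0)
  f1 <- fit_harmonics(to_climatology(s1))
  vf1 <- variance_fractions(f1, to_climatology(s1))
  expect_equal(vf1$of_total[1], 1, tolerance = 5e-3)
  expect_lt(vf1$of_total[2], 1e-10)

  s2 <- noisefree_year(mean = 0, amp1 = 3, amp2 = 3)
  vf2 <- variance_fractions(fit_harmonics(to_climatology(s2)),
                            to_climatology(s2))
  expect_equal(vf2$of_fitted, c(0.5, 0.5), tolerance = 1e-10)

  s3 <- noisefree_year(mean = 0, amp1 = 2, amp2 = 1)
  vf3 <- variance_fractions(fit_harmonics(to_climatology(s3)),
                            to_climatology(s3))
  expect_equal(vf3$of_fitted, c(0.8, 0.2), tolerance = 1e-10)
  expect_equal(vf3$of_total, c(0.8, 0.2), tolerance = 5e-3)
  expect_equal(vf3$dominant, 1L)
})

test_that("single-harmonic composite extrema have the closed form", {
  fit <- fit_harmonics(to_climatology(noisefree_year(10, 5, 200)))
  cs <- composite_extrema(fit)
  expect_equal(cs$date_of_max, 200, tolerance = 1e-4)
  expect_equal(cs$date_of_min, 17.5, tolerance = 1e-4)
  expect_equal(cs$composite_amplitude, 5, tolerance = 1e-8)
  expect_false(cs$multiple_max)
})

test_that("pure semi-annual curve reports earliest of two equal maxima", {
  s <- noisefree_year(mean = 10, amp1 = 0, amp2 = 3, dmax2 = 100)
  cs <- composite_extrema(fit_harmonics(to_climatology(s)))
  expect_equal(cs$date_of_max, 100, tolerance = 1e-3)
  expect_true(cs$multiple_max)
  expect_true(cs$multiple_min)
  expect_equal(cs$composite_amplitude, 3, tolerance = 1e-8)
})

test_that("flat curves are flagged with zero amplitude", {
  ts <- as.POSIXct("2015-01-01", tz = "UTC") + 0:364 * 86400
  cs <- composite_extrema(fit_harmonics(to_climatology(
    sample_series(ts, rep(2, 365)))))
  expect_true(cs$flat)
  expect_equal(cs$composite_amplitude, 0)
})

test_that("extrema agree with a fine-grid brute force on random curves", {
  set.seed(17)
  for (i in 1:50) {
    cf <- rnorm(4, sd = 3)
    fit <- manual_fit(rnorm(1, 10), cf[1], cf[2], cf[3], cf[4])
    cs <- composite_extrema(fit)
    bf <- brute_force_extrema(fit$mean, cf[1], cf[2], cf[3], cf[4])
    expect_lt(abs(coastclim:::circ_day_diff(cs$date_of_max,
                                            bf$date_of_max)), 0.01)
    expect_lt(abs(coastclim:::circ_day_diff(cs$date_of_min,
                                            bf$date_of_min)), 0.01)
    expect_equal(cs$value_at_max, bf$value_at_max, tolerance = 1e-6)
  }
})

test_that("composite amplitude obeys its harmonic-sum bounds", {
  set.seed(23)
  for (i in 1:50) {
    cf <- rnorm(4, sd = 2)
    fit <- manual_fit(0, cf[1], cf[2], cf[3], cf[4])
    cs <- composite_extrema(fit)
    expect_gte(cs$composite_amplitude + 1e-9,
               abs(fit$amplitude[1] - fit$amplitude[2]))
    expect_lte(cs$composite_amplitude,
               fit$amplitude[1] + fit$amplitude[2] + 1e-9)
  }
})

test_that("OLS residuals are orthogonal to the harmonic basis", {
  s <- noisy_daily(years = 5, noise_sd = 2, amp2 = 1, seed = 2)
  cl <- to_climatology(s)
  fit <- fit_harmonics(cl)
  resid <- cl$value - predict(fit, cl$doy)
  X <- coastclim:::harmonic_design(cl$doy, 2)
  expect_lt(max(abs(crossprod(X, resid))), 1e-6 * nrow(cl) * sd(cl$value))
})

test_that("fitting is invariant to observation order", {
  s <- noisy_daily(years = 4, noise_sd = 1, seed = 3)
  cl <- to_climatology(s)
  shuf <- cl[sample(nrow(cl)), ]
  f1 <- fit_harmonics(cl); f2 <- fit_harmonics(shuf)
  expect_equal(f1$amplitude, f2$amplitude, tolerance = 1e-12)
  expect_equal(f1$mean, f2$mean, tolerance = 1e-12)
})

test_that("bootstrap on noise-free data gives degenerate intervals", {
  # both harmonics present so every date element is well defined
  s <- noisefree_year(10, 5, 200, amp2 = 2, dmax2 = 100)
  ci <- bootstrap_fit(to_climatology(s), n_boot = 100, seed = 1)
  widths <- ci$ci[, "upper"] - ci$ci[, "lower"]
  expect_lt(max(widths), 1e-8)
})

test_that("bootstrap intervals are reproducible under a fixed seed", {
  cl <- to_climatology(noisy_daily(years = 3, noise_sd = 1, seed = 6))
  a <- bootstrap_fit(cl, n_boot = 50, seed = 42)
  b <- bootstrap_fit(cl, n_boot = 50, seed = 42)
  expect_identical(a$ci, b$ci)
})

test_that("bootstrap intervals bracket the point estimate", {
  cl <- to_climatology(noisy_daily(years = 3, noise_sd = 1, seed = 8))
  ci <- bootstrap_fit(cl, n_boot = 200, seed = 9)
  expect_true(all(ci$ci[, "lower"] <= ci$ci[, "point"] + 1e-9))
  expect_true(all(ci$ci[, "upper"] >= ci$ci[, "point"] - 1e-9))
})

test_that("reduced chi-squared behaves as a scaled residual variance", {
  s <- noisy_daily(years = 3, noise_sd = 1, seed = 12, mean = 0, amp1 = 3)
  cl <- to_climatology(s)
  fit <- fit_harmonics(cl)
  expect_equal(reduced_chi_squared(fit, cl, sigma = 1), 1, tolerance = 0.1)
  expect_equal(reduced_chi_squared(fit, cl, sigma = 0.5),
               4 * reduced_chi_squared(fit, cl, sigma = 1))
  # perfect fit
  s0 <- noisefree_year(10, 5, 200)
  cl0 <- to_climatology(s0)
  expect_lt(reduced_chi_squared(fit_harmonics(cl0), cl0, sigma = 1), 1e-15)
})

test_that("deseasonalizing removes exactly the fitted cycle", {
  s <- noisefree_year(10, 5, 200)
  fit <- fit_harmonics(to_climatology(s))
  an <- deseasonalize(s, fit)
  expect_lt(max(abs(an$value)), 1e-10)
  # with a trend, anomalies reproduce the trend
  st <- generate_series(synthetic_config(mean = 10, amp1 = 5, trend = 0.05,
                                         cadence = "1 day",
                                         start = "2010-01-01",
                                         end = "2019-12-31"))
  ft <- fit_harmonics(to_climatology(st))
  ant <- deseasonalize(st, ft)
  sl <- gls_trend(ant)
  # the climatological fit absorbs a small share (<1%) of a linear trend
  expect_equal(sl$slope, 0.05, tolerance = 0.02)
})
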