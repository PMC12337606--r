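# shared fixtures: small synthetic records built in code

# one year of noise-free daily data with a single annual harmonic
noisefree_year <- function(mean = 10, amp1 = 5, dmax1 = 200, amp2 = 0,
                           dmax2 = 100) {
  suppressWarnings(generate_series(synthetic_config(
    mean = mean, amp1 = amp1, amp2 = amp2, dmax1 = dmax1, dmax2 = dmax2,
    cadence = "1 day", start = "2015-01-01", end = "2015-12-31", seed = 1)))
}

# multi-year noisy daily record
noisy_daily <- function(years = 6, noise_sd = 1, amp1 = 5, amp2 = 0,
                        ar1_rho = 0, trend = 0, seed = 1, mean = 10) {
  generate_series(synthetic_config(
    mean = mean, amp1 = amp1, amp2 = amp2, dmax1 = 200, dmax2 = 100,
    trend = trend, ar1_rho = ar1_rho, noise_sd = noise_sd,
    cadence = "1 day", start = "2010-01-01",
    end = sprintf("%d-12-31", 2009 + years), seed = seed))
}

# an independent brute-force evaluation of the two-harmonic curve on a fine
# grid; used as the oracle for extrema locations
brute_force_extrema <- function(mean, a1, b1, a2, b2, step = 0.001) {
  tg <- seq(step, 365, by = step)
  y <- mean + a1 * cos(2 * pi * tg / 365) + b1 * sin(2 * pi * tg / 365) +
    a2 * cos(4 * pi * tg / 365) + b2 * sin(4 * pi * tg / 365)
  list(date_of_max = tg[which.max(y)], date_of_min = tg[which.min(y)],
       value_at_max = max(y), value_at_min = min(y))
}

# wrap a coefficient set as a harmonic_fit without fitting
manual_fit <- function(mean, a1, b1, a2, b2) {
  cf <- c(mean, a1, b1, a2, b2)
  el <- coastclim:::harmonic_elements(cf, 2)
  structure(list(K = 2, mean = el$mean, cos_coef = el$cos_coef,
                 sin_coef = el$sin_coef, amplitude = el$amplitude,
                 phase = el$phase, date_of_max = el$date_of_max),
            class = "harmonic_fit")
}
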