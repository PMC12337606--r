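# coastclim

Seasonal harmonic climatology, long-term trends, and sampling-design
experiments for coastal water-quality time series.

Coastal monitoring programs measure temperature, salinity, dissolved oxygen
and chlorophyll-a either continuously (multiparameter sondes at sub-hourly
cadence, for a few years) or manually (quarterly boat visits, for decades).
`coastclim` is for scientists who need to quantify the climatological
seasonal cycle of such records, detect long-term trends against large
seasonal and interannual variability, and answer the observing-design
question the two kinds of records pose together: **how many years of sparse
sampling does it take to pin down the seasonal cycle that a sonde measures
directly?**

## The model

Observations pooled by day of year *t* (1..365) are fit by ordinary least
squares to the annual plus semi-annual harmonic model

    y(t) = ybar + sum_{k=1,2} [ a_k cos(2*pi*k*t/365) + b_k sin(2*pi*k*t/365) ]

Each harmonic is summarised by its amplitude `C_k = sqrt(a_k^2 + b_k^2)`,
phase `atan2(b_k, a_k)`, date of maximum, and variance fraction `C_k^2/2`
over the sample variance. The composite curve's annual maximum and minimum
are located at the zero-points of its time derivative, and the composite
seasonal amplitude is half the max-minus-min range. Confidence intervals
come from a case-resampling bootstrap. Long-term trends are estimated by
generalized least squares with AR(1) errors on deseasonalized anomalies
(observation minus fitted climatology at its day of year), in units per
year. Oxygen saturation uses the Garcia-Gordon combined-fit polynomial
(Benson-Krause coefficients) so apparent oxygen utilization is
`AOU = O2_sat(T, S) - DO`.

Sampling designs are scored by Monte Carlo subsampling of a dense daily
reference: trials drawing `N` days per season are refit and compared with
the reference curve via RMSE on the 365 year-days, normalized by the SD of
the deseasonalized anomalies (nRMSE), and via the Nash-Sutcliffe efficiency
`NSE = 1 - (RMSE/sd_trial)^2`. The minimum sampling duration per harmonic
element is the smallest `N` (years of quarterly sampling) where the trial
mean at two successive grid values stays inside the reference bootstrap
confidence interval.

## Worked example

```r
library(coastclim)

# a six-year daily record: annual cycle of 10 degC amplitude peaking at
# day 200, 1.5 degC of observational noise
s <- generate_series(synthetic_config(
  mean = 15, amp1 = 10, dmax1 = 200, noise_sd = 1.5,
  cadence = "1 day", start = "2014-01-01", end = "2019-12-31", seed = 2))

fit <- fit_harmonics(to_climatology(s))
fit
#> <harmonic_fit> K=2 n=2191 mean=15.07 resid_sd=1.511
#>   k=1: C=9.967 date_of_max=200.14 var_fraction=0.955
#>   k=2: C=0.1436 date_of_max=5.81 var_fraction=0.000

composite_extrema(fit)
#> <composite_summary> max 25.17 @ day 199.51, min 5.234 @ day 18.34,
#> amplitude 9.968

trend <- gls_trend(deseasonalize(s, fit))
trend
#> <trend_result> slope=-0.01075 +/- 0.01872 per yr, p=0.566, rho=0.005,
#> n=2191 (6.0 yr)

# how long would quarterly sampling need to run to match this?
ref <- reference_fit(s, n_boot = 400, seed = 3)
dur <- sweep_duration(ref, n_trials = 200, seed = 4)
minimum_duration(dur)[6, ]
#>               element n_min attained note
#> 6 composite_amplitude     5     TRUE
```

The fitted annual amplitude (9.97 of a true 10), peak date (200.1), and a
non-significant trend (p = 0.57 for a record generated without one) read
directly off the printed objects; the duration sweep says 5 years of
quarterly sampling already brackets this low-noise record's seasonal
amplitude within the reference confidence interval.

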