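---
title: "Methods: harmonic climatology, trends, and sampling-design experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonic climatology, trends, and sampling-design experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastclim)
```

## The problem

Shallow coastal lagoons combine a large seasonal cycle, substantial
interannual variability, and monitoring records of two very different kinds:
short (a few years) high-frequency sonde records and long (decades) records
of quarterly manual sampling. `coastclim` quantifies seasonality and trends
in such records and, by subsampling the dense records at the cadence of the
sparse ones, asks how long a sparse program must run before its
climatological products are trustworthy.

## Harmonic climatology

All observations are pooled by **day of year**. We use a 365-day
climatological calendar: in leap years Feb 29 is assigned day 60 and later
dates keep their non-leap day numbers, so the annual period is exactly 365
days in every year. The model is ordinary least squares on the annual
(k = 1) and semi-annual (k = 2) harmonics,

$$y^m(t) = \bar y + \sum_{k=1}^{2}\left[a_k \cos\frac{2\pi k t}{365}
        + b_k \sin\frac{2\pi k t}{365}\right],$$

fit to **all individual observations**, not day-binned means, so years with
more data carry proportionally more weight and the residual spread is the
observation-level one used downstream. Per harmonic we report the amplitude
$C_k=\sqrt{a_k^2+b_k^2}$, the phase $\varphi_k=\mathrm{atan2}(b_k,a_k)$, and
the date of maximum $(365/2\pi k)\,\varphi_k$, mapped into $(0, 365/k]$ —
the first maximum of the year, since the k-th harmonic has k identical
maxima. A sinusoid of amplitude $C$ has variance $C^2/2$, so variance
fractions are reported both against the total sample variance (which need
not sum to 1) and against the total fitted variance (which does); the
dominant harmonic, the ratio $C_1^2 : C_2^2$, is invariant to that choice.
The date of maximum of a harmonic whose amplitude is indistinguishable from
zero is numerically meaningless; composite extrema of a flat curve are
flagged rather than reported.

**Composite extrema.** The annual maximum and minimum of the composite
curve are the zero-points of its first time derivative. The derivative of a
two-harmonic curve has at most four roots; we scan a 0.01-day grid for sign
changes and refine each bracket by bisection to below 1e-6 day. The
composite seasonal amplitude is half the max-minus-min range. Ties between
equal extrema (a pure semi-annual curve has two) report the earliest date
and set a multiplicity flag.

**Uncertainty.** Confidence intervals are percentile intervals from a
case-resampling bootstrap (default 1000 resamples): observations are drawn
with replacement and everything — coefficients, amplitudes, dates, composite
extrema — is recomputed. Case resampling is preferred to residual resampling
because seasonal heteroscedasticity (e.g. summer oxygen variability) is the
norm. Dates are circular, so each resampled date is unwrapped onto the real
line around the point estimate before quantiles are taken. The reduced
chi-squared is $\sum ((y-\hat y)/\sigma)^2 / (n - 5)$; when no measurement
$\sigma$ is supplied the fit's residual SD is used, making the statistic ~1
by construction — it becomes informative only with an independent error
estimate.

## Quality screening

Three screens precede analysis, in this order:

* **Spike filter**: a sample is removed when it differs from the *previous
  retained* sample by more than one standard deviation, the SD being that of
  the raw values in the sample's own calendar year. Comparing against the
  last retained point prevents a spike from shielding its successors.
* **Chauvenet's criterion**: under a normal model, a value is rejected when
  fewer than half an observation that extreme is expected:
  $n\,P(|Z|>|z_i|) < 0.5$. The default is a single pass; an iterate-to-
  convergence switch exists because the literature uses both conventions,
  but single-pass is the deterministic default.
* **Chlorophyll** is log10-transformed (bio-optical variables are closer to
  log-normal); nonpositive values are dropped and counted.

High-frequency records are then **daily averaged** (arithmetic mean of each
day's retained samples; empty days stay absent), which removes the diurnal
cycle. A single sample suffices for a valid daily mean by default, with the
per-day count retained so users can filter harder.

## Oxygen

Saturation uses the Garcia-Gordon combined-fit polynomial in the scaled
temperature $T_s=\ln[(298.15-T)/(273.15+T)]$ with the Benson-Krause
coefficient set. We evaluate the per-volume (cm³/dm³) coefficients and
convert to mg/L with the O2 molar mass 31.9988 g/mol over 22.3916 L/mol;
the per-mass (µmol/kg) set is available as an output option. The two
conventions differ by the seawater density factor, under 0.3 % across the
valid range (−2..40 °C, 0..42 psu). AOU = saturation − observed DO, positive
under net respiration. No diurnal-aliasing correction is applied to AOU:
daily averaging removes the diurnal cycle from dense records, and sparse
records lack the resolution to estimate one.

## Trends

Trends are estimated on deseasonalized anomalies by two-stage feasible GLS:
an OLS first pass, the AR(1) parameter taken as the lag-1 autocorrelation of
the OLS residuals **in observation order**, then one GLS refit via the
Prais-Winsten transform. Time is continuous years from the first
observation, so slopes are in units per year. The AR(1)-on-observation-
sequence assumption is appropriate for near-regular (quarterly) records and
is a documented limitation for very gappy ones; the error structure itself
is an assumption, not an inference — white-noise and AR(1) calibration are
both checked in the test suite (type-I error within [3, 7] % and at most
9 % respectively, where naive OLS under AR(1) with rho = 0.5 rejects ~25 %
of true nulls). Multi-site mean trends propagate per-site regression SEs
under independence: $SE = \sqrt{\sum se_i^2}/m$.

**Split-half shifts.** A record of at least 10 years is split at its
temporal midpoint, each half is refit, and late-minus-early differences of
every element are reported, with circular date arithmetic in
(−182.5, 182.5]. Differences are emitted for per-harmonic *and* composite
elements, since which of them a given study compares varies; group-level
contrasts use Welch two-sample t-tests.

## Subsampling experiments

Both experiments score sparse designs against a dense daily reference
(`reference_fit`: fit, composite extrema, bootstrap CIs, and the SD of
deseasonalized anomalies).

* **Density-matched**: each of 200 trials draws the stated number of days
  uniformly without replacement within each calendar quarter (Jan–Mar,
  Apr–Jun, Jul–Sep, Oct–Dec — the quarterly protocol's seasons; the pool is
  all years of the reference), refits, and is scored by RMSE between the two
  fitted curves on the 365 integer year-days with the trial's sample count
  as degrees of freedom, nRMSE (RMSE over anomaly SD), and
  NSE $=1-(\mathrm{RMSE}/sd_{trial})^2$ with the usual skill classes
  (≥ 0.90 very good, 0.80–0.90 good, 0.65–0.80 acceptable, else
  unsatisfactory).
* **Duration sweep**: for each duration `N` on a grid (default 5–50 years),
  200 trials draw `N` days per season — `N` years of quarterly sampling —
  and the per-trial harmonic elements are aggregated into means, SDs, and
  the mean nRMSE. When `N` exceeds the pooled days available in a quarter,
  draws fall back to sampling with replacement: the climatological-pooling
  regime needed to sweep durations past the reference record length.
* **nSD**: element SDs are normalized by their large-N asymptote, taken as
  the mean SD over the upper half of the duration grid. With element SDs
  decaying like $1/\sqrt N$, the nSD at the top of the default grid is
  ~0.83 by construction rather than exactly 1 — the normalization shows
  *where the decay flattens*, not a limit value.
* **Minimum duration**: the smallest grid `N` at which the trial-mean
  element at `N` *and* at the next grid value both lie inside the reference
  bootstrap CI; if never satisfied, the closest grid value is returned
  flagged as not attained. The mechanism that makes this grow with noise is
  the small-sample positive bias of amplitude estimates (a Rice-type bias
  of order $\sigma^2/(4NC)$ against a reference CI of width proportional to
  $\sigma$), so the minimum duration scales roughly linearly with the
  noise-to-signal ratio.

## The synthetic generator

`synthetic_config`/`generate_series` produce records with fully known ground
truth: mean, two harmonics (amplitudes and dates of maxima), linear trend,
optional diurnal cosine, stationary AR(1) noise generated **on the sampling
grid** (a per-step rho of r at 15-min cadence is r^96 per day), gap windows,
and spikes of ±`spike_scale`·`noise_sd` at uniformly random times recorded
in a ground-truth sidecar. Quarterly "manual" sampling is anchored near each
quarter's midpoint with ±30 days of seeded scheduling jitter at a fixed
local hour, mimicking field protocols tied to a consistent time of day (and
tidal stage); the jitter is what gives multi-year quarterly records enough
distinct days of year to support a five-parameter fit.
`generate_site_suite` builds a coherent multi-variable site: DO is
constructed as `o2_saturation(T, S)` minus an injected AOU signal plus
noise, so the oxygen module must recover the injected AOU cycle, and
chlorophyll is generated log-normally with the harmonic signal on the log10
scale.

What the generator does **not** emulate: tidal (M2/S2) constituents,
spatially correlated multi-site noise, sensor drift and biofouling, and
non-AR(1) noise structure. The AR(1) choice is an assumption to vary in
sensitivity tests, not a property inferred from real sonde data. Passing
recovery tests therefore demonstrates correctness of the estimators under
these idealized conditions, not robustness to every failure mode of field
data.

## Defaults and numerical choices

| Parameter | Default | Why |
|---|---|---|
| Harmonics `K` | 2 | annual + semi-annual carry the bulk of seasonal variance in these systems; `K` is settable but untested beyond 4 |
| Bootstrap resamples | 1000 | percentile CIs stable to ~1 % at this size |
| Extrema scan step | 0.01 d | bracket every root of a 2-harmonic derivative; refined to 1e-6 d |
| Trials per experiment | 200 | trial-mean Monte Carlo error well below the effects of interest |
| Duration grid | 5,10,15,20,25,30,40,50 yr | spans realistic program lengths up to several multiples of a dense record |
| Spike filter threshold | 1 yearly SD | literal one-SD-from-previous-point rule on raw yearly statistics |
| Chauvenet passes | 1 | deterministic; iteration available behind a switch |
| Significance | 0.05 | reporting flag only; p-values are always returned |

Degenerate inputs are contracts, not crashes: flat curves flag undefined
extrema dates with zero amplitude; a noise-free reference makes nRMSE
undefined (flagged NA); series too short for a stage (one-point spike
filter, n < 4 Chauvenet, < 3-year trends, < 10-year split halves) warn or
error with the reason named.

Test and example problem sizes (records of 1–10 years daily, 500-replicate
calibration studies, 200-trial experiments) were chosen so the full suite
documents the method at desk scale; all of them are parameters, and larger
studies only tighten the Monte Carlo bands.

## Known limitations

* The spike filter's yearly SD includes the seasonal cycle, so it is a
  conservative screen for strongly seasonal variables (large jumps near the
  seasonal slope survive). This mirrors the raw-statistics rule it
  implements.
* GLS assumes AR(1) in observation order; irregular gaps distort the
  effective autocorrelation.
* Amplitude estimates from very sparse trials are biased upward (Rice
  bias); the duration experiments measure this rather than correct it,
  because that bias is precisely what limits sparse programs.
* Dates of maxima for near-zero-amplitude harmonics are unstable; use the
  multiplicity/flat flags and variance fractions before interpreting them.
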