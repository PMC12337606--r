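Package: coastclim
Title: Seasonal Harmonic Climatology, Trends, and Sampling-Design
    Experiments for Coastal Water-Quality Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing timestamped coastal water-quality records
    (temperature, salinity, dissolved oxygen, chlorophyll-a): quality
    screening (spike filter, Chauvenet's criterion, daily averaging),
    apparent oxygen utilization from Garcia-Gordon oxygen solubility,
    two-harmonic (annual plus semi-annual) climatological fits with
    bootstrap confidence intervals and composite-curve extrema,
    generalized-least-squares trend detection on deseasonalized anomalies
    with AR(1) errors, split-record shifts in seasonal timing and
    amplitude, and Monte Carlo subsampling experiments that score sparse
    sampling designs (frequency and duration) against a dense reference
    with nRMSE, Nash-Sutcliffe efficiency, and minimum-duration criteria.
    Includes a synthetic-data generator with known ground truth so every
    stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    nlme,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
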