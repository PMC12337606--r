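#' Oxygen solubility at equilibrium with the atmosphere
#'
#' Garcia and Gordon (1992) combined-fit solubility polynomial with the
#' Benson-Krause coefficient set, evaluated in the scaled temperature
#' `Ts = ln((298.15 - T) / (273.15 + T))`. The per-volume (cm3/dm3)
#' coefficients are used; mg/L conversion multiplies by the O2 molar mass
#' 31.9988 g/mol over the molar volume 22.3916 L/mol at STP. The per-volume
#' convention differs from the per-mass (umol/kg) one by less than 0.3 % over
#' the valid range; the per-volume form is the natural match for sonde
#' concentrations reported in mg/L.
#'
#' @param temperature water temperature, degC, in [-2, 40].
#' @param salinity practical salinity, psu, in [0, 42].
#' @param units output units: `"mg/L"` (default), `"ml/L"`, or `"umol/kg"`
#'   (the per-mass Benson-Krause coefficient set).
#' @return Saturation concentration of dissolved oxygen, vectorized over
#'   `temperature` and `salinity`.
#' @export
#' @examples
#' o2_saturation(10, 35)             # ~9.02 mg/L
#' o2_saturation(10, 35, "umol/kg")  # 274.610, the published check value
o2_saturation <- function(temperature, salinity,
                          units = c("mg/L", "ml/L", "umol/kg")) {
  units <- match.arg(units)
  if (any(!is.finite(temperature)) || any(!is.finite(salinity))) {
    stop("temperature and salinity must be finite")
  }
  if (any(temperature < -2 | temperature > 40)) {
    stop("temperature outside valid range [-2, 40] degC")
  }
  if (any(salinity < 0 | salinity > 42)) {
    stop("salinity outside valid range [0, 42] psu")
  }
  if (units == "umol/kg") {
    a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
    b <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
    c0 <- -2.75915e-7
  } else {
    a <- c(2.00907, 3.22014, 4.05010, 4.94457, -2.56847e-1, 3.88767)
    b <- c(-6.24523e-3, -7.37614e-3, -1.03410e-2, -8.17083e-3)
    c0 <- -4.88682e-7
  }
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  lnc <- a[1] + ts * (a[2] + ts * (a[3] + ts * (a[4] + ts * (a[5] + ts * a[6])))) +
    salinity * (b[1] + ts * (b[2] + ts * (b[3] + ts * b[4]))) +
    c0 * salinity^2
  conc <- exp(lnc)                      # ml/L or umol/kg
  if (units == "mg/L") conc <- conc * 31.9988 / 22.3916
  conc
}

#' Apparent oxygen utilization
#'
#' AOU is the oxygen saturation concentration at in-situ temperature and
#' salinity minus the observed dissolved-oxygen concentration. Positive values
#' indicate a net oxygen deficit (net respiration); negative values indicate
#' supersaturation (net production / bubble injection).
#'
#' @param temperature degC. @param salinity psu.
#' @param do_obs observed dissolved oxygen, mg/L, >= 0.
#' @return AOU in mg/L, vectorized.
#' @export
aou <- function(temperature, salinity, do_obs) {
  if (any(do_obs < 0, na.rm = TRUE)) stop("do_obs must be >= 0")
  o2_saturation(temperature, salinity) - do_obs
}

#' Derive an AOU series from temperature, salinity and dissolved oxygen
#'
#' The three input series must share an identical time base.
#'
#' @param temp,sal,do_series `sample_series` objects on the same timestamps.
#' @return A `sample_series` of AOU (mg/L).
#' @export
derive_aou_series <- function(temp, sal, do_series) {
  if (nrow(temp) != nrow(sal) || nrow(temp) != nrow(do_series) ||
      any(temp$timestamp != sal$timestamp) ||
      any(temp$timestamp != do_series$timestamp)) {
    stop("temperature, salinity and DO series must share one time base")
  }
  sample_series(temp$timestamp,
                aou(temp$value, sal$value, do_series$value),
                site = attr(temp, "site"), variable = "aou")
}
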