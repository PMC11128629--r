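#' Boltzmann constant, exact 2019 SI value (J/K). Not configurable.
#' @keywords internal
k_B <- 1.380649e-23

#' Cleft resistance from adhesion noise
#'
#' The electrolyte-filled cleft between an adherent cell membrane and the
#' sensor oxide behaves as an ohmic resistor whose Johnson-Nyquist thermal
#' noise is the cell adhesion noise. Its one-sided voltage-noise PSD is
#' `4 k_B T R`, so the cleft resistance follows from the measured adhesion
#' noise plateau as
#'
#'   `R_cleft = delta_sv / (4 k_B T)`
#'
#' With the plateau amplitude 0.027 uV^2/Hz (2.7e-14 V^2/Hz) at incubation
#' temperature (310.15 K) this gives 1.58 MOhm.
#'
#' @param delta_sv Adhesion noise in V^2/Hz (one-sided); must be >= 0.
#'   Negative estimates occur in raw spectra; clamp or reject them before
#'   calling (the error message says so).
#' @param temperature Absolute temperature in kelvin, > 0. Default 310.15 K
#'   (37 C).
#' @return Cleft resistance in ohms. Vectorized over `delta_sv`.
#' @seealso [johnson_psd()] for the exact inverse.
#' @export
#' @examples
#' cleft_resistance(2.7e-14, 310.15) / 1e6   # ~1.58 MOhm
cleft_resistance <- function(delta_sv, temperature = 310.15) {
  if (any(!is.finite(delta_sv)))
    stop("`delta_sv` must be finite", call. = FALSE)
  if (any(delta_sv < 0))
    stop("`delta_sv` is negative: clamp to zero or reject the sensor before converting to a resistance",
         call. = FALSE)
  if (any(temperature <= 0))
    stop("`temperature` must be positive (kelvin)", call. = FALSE)
  delta_sv / (4 * k_B * temperature)
}

#' Johnson-Nyquist one-sided voltage-noise PSD of a resistor
#'
#' `S_V = 4 k_B T R`, the exact inverse of [cleft_resistance()].
#'
#' @param resistance Resistance in ohms, >= 0.
#' @param temperature Absolute temperature in kelvin, > 0.
#' @return One-sided PSD in V^2/Hz. Vectorized over `resistance`.
#' @export
#' @examples
#' uV2_per_Hz(johnson_psd(1.58e6, 310.15))   # ~0.027 uV^2/Hz
johnson_psd <- function(resistance, temperature = 310.15) {
  if (any(!is.finite(resistance) | resistance < 0))
    stop("`resistance` must be finite and non-negative", call. = FALSE)
  if (any(temperature <= 0))
    stop("`temperature` must be positive (kelvin)", call. = FALSE)
  4 * k_B * temperature * resistance
}
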