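#' Spatial-peak pulse-average acoustic intensity
#'
#' Converts a spatial-peak pressure amplitude into the spatial-peak
#' pulse-average intensity of a plane wave, \eqn{I_{SPPA} = p^2 / (2 Z)},
#' expressed in W/cm^2. The default impedance is that of water
#' (\eqn{Z \approx 1.5 \times 10^6} Rayls), the medium in which free-field
#' hydrophone calibrations are performed.
#'
#' @param pressure_pa spatial-peak pressure amplitude in pascals (>= 0).
#' @param impedance_rayl acoustic impedance in Rayls (kg m^-2 s^-1), > 0.
#' @return intensity in W/cm^2.
#' @examples
#' isppa(522e3) # 522 kPa in water: ~9.08 W/cm^2
#' @export
isppa <- function(pressure_pa, impedance_rayl = 1.5e6) {
  if (any(pressure_pa < 0)) abort("pressure must be non-negative")
  if (any(impedance_rayl <= 0)) abort("acoustic impedance must be positive")
  pressure_pa^2 / (2 * impedance_rayl) / 1e4
}

#' Spatial-peak temporal-average intensity
#'
#' Scales a pulse-average intensity by the stimulation duty cycle.
#'
#' @param isppa pulse-average intensity in W/cm^2 (>= 0).
#' @param duty_cycle fraction of time the pulse is on, in \[0, 1\].
#' @return intensity in W/cm^2.
#' @examples
#' ispta(10, 0.2) # 2 W/cm^2
#' @export
ispta <- function(isppa, duty_cycle) {
  if (any(isppa < 0)) abort("intensity must be non-negative")
  if (any(duty_cycle < 0 | duty_cycle > 1)) abort("duty cycle must be in [0, 1]")
  isppa * duty_cycle
}
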