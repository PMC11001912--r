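#' Convert between Raman shift and absolute wavelength
#'
#' The Raman shift of a scattered line is the wavenumber difference between
#' excitation and scattered photon, `shift = 1e7/laser_nm - 1e7/line_nm`
#' (shift in cm^-1, wavelengths in nm). `shift_to_wavelength()` maps a shift
#' to the absolute wavelength it lands on for a given excitation wavelength;
#' `wavelength_to_shift()` is its exact inverse.
#'
#' @param laser_nm excitation wavelength in nm (> 0).
#' @param shift_cm1 Raman shift in cm^-1.
#' @param line_nm absolute wavelength of the scattered line in nm (> 0).
#' @return wavelength in nm, or Raman shift in cm^-1.
#' @export
#' @examples
#' shift_to_wavelength(785, 1001.4)   # the strong polystyrene line
#' wavelength_to_shift(785, shift_to_wavelength(785, 1001.4))
shift_to_wavelength <- function(laser_nm, shift_cm1) {
  if (any(laser_nm <= 0)) abort("laser wavelength must be positive")
  nu <- 1e7 / laser_nm - shift_cm1
  if (any(nu <= 0)) abort("resulting wavenumber is non-positive")
  1e7 / nu
}

#' @rdname shift_to_wavelength
#' @export
wavelength_to_shift <- function(laser_nm, line_nm) {
  if (any(laser_nm <= 0) || any(line_nm <= 0)) {
    abort("wavelengths must be positive")
  }
  1e7 / laser_nm - 1e7 / line_nm
}

#' Relative blackbody spectral radiance
#'
#' Planck's law per unit wavelength on an arbitrary common scale. Only ratios
#' of this quantity are used (for the lamp-based instrument response
#' correction), so physical prefactors are dropped.
#'
#' @param temperature_K blackbody temperature in kelvin (> 0).
#' @param wavelength_nm wavelength(s) in nm (> 0).
#' @return relative radiance (arbitrary units, proportional to the physical
#'   spectral radiance).
#' @export
#' @examples
#' planck_radiance(3000, c(800, 960))
planck_radiance <- function(temperature_K, wavelength_nm) {
  if (any(temperature_K <= 0) || any(wavelength_nm <= 0)) {
    abort("temperature and wavelength must be positive")
  }
  hc_over_k <- 1.438777e7 # nm K (second radiation constant)
  x <- hc_over_k / (wavelength_nm * temperature_K)
  1e27 / (wavelength_nm^5 * (exp(x) - 1))
}
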