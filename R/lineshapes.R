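#' Combined FWHM of a Voigt profile
#'
#' Olivero-Longbothum approximation,
#' `f_V = 0.5346 f_L + sqrt(0.2166 f_L^2 + f_G^2)`, accurate to better than
#' 0.02% over all mixing ratios.
#'
#' @param gauss_fwhm,lorentz_fwhm Gaussian and Lorentzian component FWHM
#'   (same units, >= 0; at least one > 0).
#' @return the FWHM of the combined profile.
#' @export
voigt_fwhm <- function(gauss_fwhm, lorentz_fwhm) {
  if (any(gauss_fwhm < 0) || any(lorentz_fwhm < 0)) {
    abort("component widths must be non-negative")
  }
  0.5346 * lorentz_fwhm + sqrt(0.2166 * lorentz_fwhm^2 + gauss_fwhm^2)
}

#' Unit-area line profiles
#'
#' Gaussian, Lorentzian and pseudo-Voigt profiles parameterized by FWHM,
#' each normalized to unit integrated area. The pseudo-Voigt is the
#' eta-weighted mix of a unit-area Lorentzian and Gaussian of the combined
#' [voigt_fwhm()] width, with the Thompson-Cox-Hastings mixing parameter.
#'
#' @param x evaluation points.
#' @param center line center.
#' @param fwhm full width at half maximum (same units as `x`).
#' @param gauss_fwhm,lorentz_fwhm component widths of the pseudo-Voigt.
#' @return profile values; integrates to 1 over an unbounded axis.
#' @export
gauss_profile <- function(x, center, fwhm) {
  stats::dnorm(x, center, fwhm / (2 * sqrt(2 * log(2))))
}

#' @rdname gauss_profile
#' @export
lorentz_profile <- function(x, center, fwhm) {
  stats::dcauchy(x, center, fwhm / 2)
}

#' @rdname gauss_profile
#' @export
pseudo_voigt_profile <- function(x, center, gauss_fwhm, lorentz_fwhm) {
  f <- voigt_fwhm(gauss_fwhm, lorentz_fwhm)
  r <- lorentz_fwhm / f
  eta <- 1.36603 * r - 0.47719 * r^2 + 0.11116 * r^3
  eta * lorentz_profile(x, center, f) + (1 - eta) * gauss_profile(x, center, f)
}

# Evaluate one catalog line (unit area) on an axis. `row` is one row of a
# line-list tibble.
line_profile <- function(x, center, row) {
  switch(row$shape,
         gaussian = gauss_profile(x, center, row$fwhm_cm1),
         lorentzian = lorentz_profile(x, center, row$fwhm_cm1),
         voigt = pseudo_voigt_profile(x, center, row$gauss_fwhm, row$lorentz_fwhm),
         abort(paste0("unknown line shape: ", row$shape)))
}

#' Build a line list
#'
#' A line list describes a material's Raman lines: center position (cm^-1),
#' relative integrated intensity, FWHM (cm^-1) and profile family. Voigt
#' lines carry separate Gaussian and Lorentzian component widths; their
#' effective `fwhm_cm1` is filled in via [voigt_fwhm()].
#'
#' @param material material name.
#' @param lines a data frame with columns `center_cm1`, `rel_intensity`,
#'   `fwhm_cm1`, `shape` (`gaussian`/`lorentzian`/`voigt`) and, for Voigt
#'   lines, `gauss_fwhm` and `lorentz_fwhm`.
#' @return a tibble of class `line_list` (attribute `material`), sorted by
#'   center.
#' @export
line_list <- function(material, lines) {
  lines <- tibble::as_tibble(lines)
  need <- c("center_cm1", "rel_intensity", "fwhm_cm1", "shape")
  if (!all(need %in% names(lines))) {
    abort(paste("line list needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(lines) < 1) abort("line list needs at least one line")
  if (anyDuplicated(lines$center_cm1)) abort("line centers must be unique")
  if (!all(lines$shape %in% c("gaussian", "lorentzian", "voigt"))) {
    abort("shape must be gaussian, lorentzian or voigt")
  }
  if (!"gauss_fwhm" %in% names(lines)) lines$gauss_fwhm <- NA_real_
  if (!"lorentz_fwhm" %in% names(lines)) lines$lorentz_fwhm <- NA_real_
  v <- lines$shape == "voigt"
  if (any(v)) {
    if (any(is.na(lines$gauss_fwhm[v])) || any(is.na(lines$lorentz_fwhm[v])) ||
        any(lines$gauss_fwhm[v] <= 0) || any(lines$lorentz_fwhm[v] <= 0)) {
      abort("voigt lines need positive gauss_fwhm and lorentz_fwhm")
    }
    lines$fwhm_cm1[v] <- voigt_fwhm(lines$gauss_fwhm[v], lines$lorentz_fwhm[v])
  }
  if (any(lines$fwhm_cm1 <= 0) || any(lines$rel_intensity < 0)) {
    abort("fwhm_cm1 must be > 0 and rel_intensity >= 0")
  }
  lines <- dplyr::arrange(lines, .data$center_cm1)
  class(lines) <- c("line_list", class(lines))
  attr(lines, "material") <- material
  lines
}

#' Read or write a line list as JSON
#' @param path JSON file path.
#' @param x a `line_list`.
#' @return `read_linelist` returns a `line_list`.
#' @export
read_linelist <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  line_list(j$material, tibble::as_tibble(j$lines))
}

#' @rdname read_linelist
#' @export
write_linelist <- function(x, path) {
  jsonlite::write_json(
    list(material = attr(x, "material"),
         lines = as.data.frame(x)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Built-in reference line lists
#'
#' Line lists shipped with the package: `polystyrene` (the built-in
#' calibration reference; ASTM E1840 consensus band positions),
#' `polypropylene`, `toluene` and `diamond` (single Lorentzian line at
#' 1332 cm^-1, natural FWHM 1.8 cm^-1, used to measure the apparatus
#' function).
#'
#' @param material one of `"polystyrene"`, `"polypropylene"`, `"toluene"`,
#'   `"diamond"`.
#' @return a `line_list`.
#' @export
#' @examples
#' builtin_linelist("polystyrene")
builtin_linelist <- function(material = c("polystyrene", "polypropylene",
                                          "toluene", "diamond")) {
  material <- match.arg(material)
  read_linelist(system.file("extdata", paste0(material, ".json"),
                            package = "reframan", mustWork = TRUE))
}

#' Synthesize a spectrum from a line list
#'
#' Evaluates the sum of analytic line profiles (each with integrated area
#' `rel_intensity * amplitude`) on the given axis, plus an optional baseline.
#' On a wavelength axis the line centers and widths are converted through the
#' supplied excitation wavelength.
#'
#' @param lines a `line_list`.
#' @param axis numeric axis values (strictly increasing).
#' @param kind `"raman_shift_cm1"` or `"wavelength_nm"`.
#' @param laser_nm excitation wavelength; required when `kind` is
#'   `"wavelength_nm"`.
#' @param amplitude overall area scale applied to every line.
#' @param baseline optional `raman_spectrum` on the same axis kind to add
#'   (resampled onto `axis`).
#' @param channel,exposure_s,acquisition metadata passed to the result.
#' @return a `raman_spectrum`. Lines whose center falls outside the axis span
#'   are skipped with a warning.
#' @export
synthesize_spectrum <- function(lines, axis,
                                kind = c("raman_shift_cm1", "wavelength_nm"),
                                laser_nm = NULL, amplitude = 1, baseline = NULL,
                                channel = "main", exposure_s = 1,
                                acquisition = NA_character_) {
  kind <- match.arg(kind)
  if (kind == "wavelength_nm" && is.null(laser_nm)) {
    abort("laser_nm is required for a wavelength axis")
  }
  y <- numeric(length(axis))
  for (i in seq_len(nrow(lines))) {
    row <- lines[i, ]
    if (kind == "raman_shift_cm1") {
      center <- row$center_cm1
      scale <- 1
    } else {
      center <- shift_to_wavelength(laser_nm, row$center_cm1)
      # local Jacobian d(lambda)/d(nu~): widths in nm, area preserved
      scale <- center^2 / 1e7
    }
    if (center < min(axis) || center > max(axis)) {
      warn(sprintf("line at %.1f outside axis span; skipped", center))
      next
    }
    prof <- switch(row$shape,
      gaussian = gauss_profile(axis, center, row$fwhm_cm1 * scale),
      lorentzian = lorentz_profile(axis, center, row$fwhm_cm1 * scale),
      voigt = pseudo_voigt_profile(axis, center, row$gauss_fwhm * scale,
                                   row$lorentz_fwhm * scale))
    y <- y + amplitude * row$rel_intensity * prof
  }
  if (!is.null(baseline)) {
    y <- y + resample_spectrum(baseline, axis, fill = 0)$intensity
  }
  raman_spectrum(axis, y, kind, channel = channel, exposure_s = exposure_s,
                 acquisition = acquisition)
}

#' Resample a spectrum onto a new axis
#'
#' Piecewise-linear interpolation. Target points outside the source support
#' take `fill` and are flagged in the logical attribute `mask` (TRUE =
#' extrapolated/filled).
#'
#' @param x a `raman_spectrum`.
#' @param target_axis numeric, strictly increasing; same axis kind as `x`.
#' @param fill value for points outside the source support.
#' @return a `raman_spectrum` on `target_axis` with attribute `mask`.
#' @export
resample_spectrum <- function(x, target_axis, fill = 0) {
  if (max(target_axis) < min(x$axis) || min(target_axis) > max(x$axis)) {
    abort("target axis does not overlap the source axis")
  }
  y <- stats::approx(x$axis, x$intensity, xout = target_axis,
                     method = "linear", rule = 1)$y
  mask <- is.na(y)
  y[mask] <- fill
  out <- spectrum_like(x, axis = target_axis, intensity = y)
  attr(out, "mask") <- mask
  out
}
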