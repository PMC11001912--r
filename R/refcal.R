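#' Fit the reference-channel polystyrene peaks
#'
#' For each catalog line, predicts its pixel position from the nominal laser
#' wavelength and the factory pixel-to-wavelength map, then least-squares
#' fits a single pseudo-Voigt profile (amplitude, center, FWHM, mixing,
#' constant baseline) in a window around the prediction. Failed fits are
#' flagged and excluded downstream.
#'
#' @param ref_spectrum reference-channel `raman_spectrum` on a pixel axis.
#' @param lines reference [line_list()].
#' @param optics the [optics_model()] (factory map, treated as known).
#' @param nominal_nm nominal laser wavelength; must be within
#'   `search_halfwidth_nm` of the true one.
#' @param search_halfwidth_nm half-width of the fit window, in nm.
#' @return a tibble of class `peak_fits`: one row per catalog line with
#'   `line_cm1`, `center_px`, `center_nm`, `amplitude`, `fwhm_px`, `rmse`,
#'   `success`. Errors if fewer than 3 fits succeed.
#' @export
fit_reference_peaks <- function(ref_spectrum, lines, optics,
                                nominal_nm = 785, search_halfwidth_nm = 1) {
  if (axis_kind(ref_spectrum) != "pixel") abort("reference spectrum must be on a pixel axis")
  n_px <- nrow(ref_spectrum)
  fits <- purrr::map_dfr(seq_len(nrow(lines)), function(i) {
    row <- lines[i, ]
    fail <- tibble::tibble(line_cm1 = row$center_cm1, center_px = NA_real_,
                           center_nm = NA_real_, amplitude = NA_real_,
                           fwhm_px = NA_real_, rmse = NA_real_,
                           success = FALSE)
    nu <- 1e7 / nominal_nm - row$center_cm1
    if (nu <= 0) return(fail)
    pred_col <- col_of_wavelength(optics, 1e7 / nu, n_px)
    if (is.na(pred_col)) return(fail)
    half_px <- ceiling(search_halfwidth_nm / dispersion_of_col(optics, pred_col))
    win <- ref_spectrum$axis >= pred_col - half_px &
      ref_spectrum$axis <= pred_col + half_px
    xa <- ref_spectrum$axis[win]
    ya <- ref_spectrum$intensity[win]
    if (length(xa) < 8 || max(ya) <= min(ya)) return(fail)
    b0 <- stats::quantile(ya, 0.1, names = FALSE)
    a0 <- max(ya) - b0
    c0 <- xa[which.max(ya)]
    f0 <- max(3, sum(ya - b0 > a0 / 2))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ya ~ b + a * (eta * lorentz_profile(xa, c, f) +
                        (1 - eta) * gauss_profile(xa, c, f)),
        start = list(b = b0, a = a0 * f0, c = c0, f = f0, eta = 0.2),
        lower = c(-Inf, 0, min(xa), 1, 0), upper = c(Inf, Inf, max(xa), 10 * f0, 1),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(fail)
    cf <- stats::coef(fit)
    if (cf[["a"]] <= 0 || cf[["c"]] <= min(xa) + 0.5 || cf[["c"]] >= max(xa) - 0.5) {
      return(fail)
    }
    tibble::tibble(line_cm1 = row$center_cm1, center_px = cf[["c"]],
                   center_nm = wavelength_of_col(optics, cf[["c"]]),
                   amplitude = cf[["a"]], fwhm_px = cf[["f"]],
                   rmse = rms(stats::residuals(fit)), success = TRUE)
  })
  if (sum(fits$success) < 3) {
    abort("calibration degraded: fewer than 3 reference peaks fitted")
  }
  class(fits) <- c("peak_fits", class(fits))
  fits
}

#' Estimate the laser wavenumber from fitted reference peaks
#'
#' Each successfully fitted peak votes for the laser wavenumber through its
#' known Raman shift: `nu_laser = 1e7/lambda_fit + shift_known`. The
#' estimate is the median over peaks, after a single MAD-based outlier
#' rejection pass (> 3 x MAD). Residual spread above 5 cm^-1 after
#' rejection raises an unstable-calibration error.
#'
#' @param fits a `peak_fits` tibble from [fit_reference_peaks()].
#' @param acquisition acquisition id recorded in the result.
#' @return a `calibration_result`: list with `laser_nu_cm1`, `laser_nm`,
#'   per-peak `residuals_cm1` (used peaks), `n_peaks`, `intensity_scale`
#'   (NA until [normalize_intensity()] fills it) and `acquisition`.
#' @export
estimate_laser_wavenumber <- function(fits, acquisition = NA_character_) {
  ok <- fits$success & !is.na(fits$center_nm)
  if (sum(ok) < 3) abort("calibration degraded: fewer than 3 usable peaks")
  nu <- 1e7 / fits$center_nm[ok] + fits$line_cm1[ok]
  est <- stats::median(nu)
  dev <- abs(nu - est)
  madv <- stats::mad(nu)
  keep <- if (madv > 0) dev <= 3 * madv else rep(TRUE, length(nu))
  if (sum(keep) >= 3) {
    nu <- nu[keep]
    est <- stats::median(nu)
  }
  resid <- nu - est
  if (max(abs(resid)) > 5) {
    abort("unstable calibration: residual spread exceeds 5 cm^-1")
  }
  structure(list(laser_nu_cm1 = est, laser_nm = 1e7 / est,
                 residuals_cm1 = resid, n_peaks = length(nu),
                 intensity_scale = NA_real_, acquisition = acquisition),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration: laser %.4f nm (%.2f cm^-1), %d peaks, residual sd %.3f cm^-1>\n",
    x$laser_nm, x$laser_nu_cm1, x$n_peaks, stats::sd(x$residuals_cm1)))
  invisible(x)
}

#' Tidy and summarize a calibration result
#' @param x a `calibration_result`.
#' @param ... unused.
#' @return `tidy()`: one row per used peak with its residual; `glance()`:
#'   a one-row summary.
#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) {
  tibble::tibble(peak = seq_along(x$residuals_cm1),
                 residual_cm1 = x$residuals_cm1)
}

#' @rdname tidy.calibration_result
#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(laser_nm = x$laser_nm, laser_nu_cm1 = x$laser_nu_cm1,
                 n_peaks = x$n_peaks,
                 residual_sd_cm1 = stats::sd(x$residuals_cm1),
                 intensity_scale = x$intensity_scale)
}

#' Calibrate a pixel spectrum onto the Raman-shift axis
#'
#' Converts the pixel axis to Raman shift through the estimated laser
#' wavenumber, `shift(px) = nu_laser - 1e7/lambda(px)`, and resamples onto
#' the uniform working grid (0.5 cm^-1 step intersected with the covered
#' range). Because the laser estimate comes from the simultaneously acquired
#' reference channel, Raman features are pinned regardless of laser drift.
#'
#' @param x `raman_spectrum` on a pixel axis (main or reference channel).
#' @param calibration a `calibration_result`.
#' @param optics the [optics_model()].
#' @param grid target Raman-shift grid; default the standard 0.5 cm^-1 grid
#'   clipped to the range the spectrum covers.
#' @return a `raman_spectrum` on a Raman-shift axis.
#' @export
calibrate_shift_axis <- function(x, calibration, optics, grid = NULL) {
  if (axis_kind(x) != "pixel") abort("expected a pixel-axis spectrum")
  shift <- calibration$laser_nu_cm1 - 1e7 / wavelength_of_col(optics, x$axis)
  src <- raman_spectrum(shift, x$intensity, "raman_shift_cm1",
                        channel = attr(x, "channel") %||% "main",
                        exposure_s = attr(x, "exposure_s") %||% 1,
                        acquisition = calibration$acquisition)
  if (is.null(grid)) {
    g <- standard_shift_grid()
    grid <- g[g >= min(shift) & g <= max(shift)]
  }
  resample_spectrum(src, grid, fill = 0)
}

#' Integrated area of a designated reference peak
#'
#' Trapezoidal area above a linear baseline interpolated between the
#' medians of two flanking bands (median anchors keep the area estimate
#' insensitive to single-pixel noise at the window edges).
#'
#' @param x calibrated `raman_spectrum`.
#' @param line_cm1 peak position.
#' @param halfwidth_cm1 integration half-width.
#' @param flank_cm1 width of the baseline bands beyond the window.
#' @return area (counts x cm^-1).
#' @export
ref_peak_area <- function(x, line_cm1 = 1001.4, halfwidth_cm1 = 15,
                          flank_cm1 = 8) {
  w <- x$axis >= line_cm1 - halfwidth_cm1 & x$axis <= line_cm1 + halfwidth_cm1
  if (sum(w) < 5) abort("reference peak window not covered")
  a <- x$axis[w]
  y <- x$intensity[w]
  lw <- x$axis >= line_cm1 - halfwidth_cm1 - flank_cm1 &
    x$axis < line_cm1 - halfwidth_cm1
  rw <- x$axis > line_cm1 + halfwidth_cm1 &
    x$axis <= line_cm1 + halfwidth_cm1 + flank_cm1
  if (sum(lw) >= 3 && sum(rw) >= 3) {
    xl <- stats::median(x$axis[lw])
    xr <- stats::median(x$axis[rw])
    yl <- stats::median(x$intensity[lw])
    yr <- stats::median(x$intensity[rw])
    base <- yl + (yr - yl) * (a - xl) / (xr - xl)
  } else {
    base <- y[1] + (y[length(y)] - y[1]) * (a - a[1]) / (a[length(a)] - a[1])
  }
  pracma::trapz(a, y - base)
}

#' Normalize the main channel for laser power fluctuation
#'
#' The integrated area of a designated strong reference line (default the
#' 1001.4 cm^-1 polystyrene line) tracks the delivered laser power during
#' the exact exposure of the acquisition; dividing a baseline area by the
#' per-acquisition area gives the intensity scale applied to the main
#' channel.
#'
#' @param main calibrated main-channel `raman_spectrum`.
#' @param ref calibrated reference-channel `raman_spectrum` from the same
#'   acquisition.
#' @param baseline_ref_area reference area measured at nominal power (same
#'   units as [ref_peak_area()]).
#' @param calibration optional `calibration_result` to record the scale in.
#' @param line_cm1,halfwidth_cm1 designated line and window.
#' @return the scaled main spectrum, with attribute `intensity_scale`; if
#'   `calibration` is supplied the updated result is attached as attribute
#'   `calibration`.
#' @export
normalize_intensity <- function(main, ref, baseline_ref_area,
                                calibration = NULL, line_cm1 = 1001.4,
                                halfwidth_cm1 = 15) {
  if (baseline_ref_area <= 0) abort("baseline reference area must be positive")
  area <- ref_peak_area(ref, line_cm1, halfwidth_cm1)
  if (area <= 0) abort("reference peak area is non-positive")
  scale <- baseline_ref_area / area
  out <- spectrum_like(main, intensity = main$intensity * scale)
  attr(out, "intensity_scale") <- scale
  if (!is.null(calibration)) {
    calibration$intensity_scale <- scale
    attr(out, "calibration") <- calibration
  }
  out
}

#' Instrument response from a blackbody lamp measurement
#'
#' Divides a measured tungsten-halogen lamp spectrum by the Planck radiance
#' at the lamp's color temperature and max-normalizes, giving the relative
#' spectral response (optics transmittance x sensor QE) on the wavelength
#' axis.
#'
#' @param lamp measured lamp `raman_spectrum` on a wavelength (nm) axis,
#'   strictly positive.
#' @param temperature_K lamp blackbody temperature (default 3000 K).
#' @return a tibble of class `response_curve` with `wavelength_nm` and
#'   `response` (max 1, strictly positive).
#' @export
build_response_curve <- function(lamp, temperature_K = 3000) {
  if (axis_kind(lamp) != "wavelength_nm") abort("lamp spectrum must be on a nm axis")
  if (any(lamp$intensity <= 0)) abort("lamp spectrum must be strictly positive")
  r <- lamp$intensity / planck_radiance(temperature_K, lamp$axis)
  out <- tibble::tibble(wavelength_nm = lamp$axis, response = r / max(r))
  class(out) <- c("response_curve", class(out))
  out
}

#' Apply (or invert) a response correction
#'
#' Divides a spectrum by the relative instrument response interpolated at
#' each point's absolute wavelength. For a Raman-shift axis the wavelengths
#' are obtained through the calibrated laser wavelength.
#'
#' @param x a `raman_spectrum` on a nm or Raman-shift axis.
#' @param curve a `response_curve`.
#' @param laser_nm excitation wavelength; required for a Raman-shift axis.
#' @param invert multiply instead of divide (exact inverse of applying).
#' @return the corrected `raman_spectrum`.
#' @export
apply_response <- function(x, curve, laser_nm = NULL, invert = FALSE) {
  lam <- switch(axis_kind(x),
                wavelength_nm = x$axis,
                raman_shift_cm1 = {
                  if (is.null(laser_nm)) abort("laser_nm needed for a shift axis")
                  shift_to_wavelength(laser_nm, x$axis)
                },
                abort("response correction needs a nm or shift axis"))
  r <- stats::approx(curve$wavelength_nm, curve$response, xout = lam,
                     rule = 2)$y
  y <- if (invert) x$intensity * r else x$intensity / r
  spectrum_like(x, intensity = y)
}

#' High-frequency (QE-like) noise metric
#'
#' Standard deviation of the residual from a Savitzky-Golay smooth (window
#' 11, order 3) inside a peak-free window: static pixel-to-pixel QE
#' variation shows up as exactly this kind of spectrally sharp structure on
#' smooth backgrounds.
#'
#' @param x a `raman_spectrum`.
#' @param quiet_window axis range free of Raman lines.
#' @return numeric scalar.
#' @export
qe_noise_metric <- function(x, quiet_window = c(1650, 2150)) {
  w <- x$axis >= quiet_window[1] & x$axis <= quiet_window[2]
  if (sum(w) < 21) abort("quiet window too small")
  y <- x$intensity[w]
  stats::sd(y - signal::sgolayfilt(y, p = 3, n = 11))
}

#' Average drift-shifted calibrated spectra
#'
#' Once each acquisition is recalibrated from the reference channel, a given
#' Raman shift falls on a different sensor pixel whenever the laser has
#' drifted, so the static pixel-to-pixel QE variation decorrelates across
#' acquisitions and averages down roughly as sqrt(M) over M distinct pixel
#' alignments, while Raman features (pinned by calibration) add coherently.
#'
#' @param spectra list of calibrated `raman_spectrum`s on a common grid.
#' @param calibrations optional list of `calibration_result`s used to check
#'   that the laser positions actually span some drift.
#' @param quiet_window passed to [qe_noise_metric()] for the noise report.
#' @return a list with `mean` (the averaged `raman_spectrum`), and `report`
#'   (tibble: QE-noise metric before (mean over inputs) and after).
#' @export
drift_average <- function(spectra, calibrations = NULL,
                          quiet_window = c(1650, 2150)) {
  if (length(spectra) < 2) abort("need at least 2 spectra")
  ax <- spectra[[1]]$axis
  for (s in spectra[-1]) {
    if (length(s$axis) != length(ax) || any(s$axis != ax)) {
      abort("spectra must share a common grid")
    }
  }
  if (!is.null(calibrations)) {
    nus <- vapply(calibrations, `[[`, numeric(1), "laser_nu_cm1")
    if (diff(range(nus)) < 0.5) {
      warn("QE averaging ineffective: laser positions span < 1 grid step")
    }
  }
  m <- rowMeans(vapply(spectra, function(s) s$intensity,
                       numeric(length(ax))))
  avg <- spectrum_like(spectra[[1]], intensity = m)
  before <- mean(vapply(spectra, qe_noise_metric, numeric(1),
                        quiet_window = quiet_window))
  after <- qe_noise_metric(avg, quiet_window)
  list(mean = avg,
       report = tibble::tibble(n_spectra = length(spectra),
                               qe_noise_before = before,
                               qe_noise_after = after,
                               reduction = before / after))
}
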