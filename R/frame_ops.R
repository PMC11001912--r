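#' Extract a spectral band from a frame
#'
#' Column-wise sum over a row window (software full-vertical binning of the
#' band), yielding a pixel-axis spectrum. Binning is exact integer summation.
#'
#' @param frame a `sensor_frame`.
#' @param rows row window: a vector of 0-based row indices (as used by
#'   [optics_model()]), or a channel name `"reference"`, `"main"`,
#'   `"offset"` resolved through `optics`.
#' @param optics an [optics_model()], required when `rows` is a channel
#'   name.
#' @return a `raman_spectrum` on a pixel axis; metadata records the window
#'   and the frame's exposure.
#' @export
extract_channel <- function(frame, rows = "main", optics = NULL) {
  channel <- "main"
  if (is.character(rows)) {
    if (is.null(optics)) abort("optics needed to resolve a named band")
    channel <- rows
    rows <- switch(rows, reference = optics$ref_rows, main = optics$main_rows,
                   offset = optics$offset_rows,
                   abort("unknown band name"))
  }
  if (length(rows) == 0) abort("empty row window")
  rr <- rows + 1L
  if (any(rr < 1) || any(rr > nrow(frame$counts))) {
    abort("row window outside the frame")
  }
  m <- frame$counts[rr, , drop = FALSE]
  out <- raman_spectrum(seq_len(ncol(m)), colSums(m), kind = "pixel",
                        channel = channel,
                        exposure_s = frame$sidecar$exposure_s %||% 1)
  attr(out, "row_window") <- rows
  out
}

#' Remove hot pixels by rolling-median thresholding
#'
#' Values exceeding the rolling median by more than `k_sigma` times a robust
#' local scale (MAD of the residual from the rolling median) are replaced by
#' the rolling median. Genuine Raman lines at documented widths survive the
#' default `k_sigma = 8`. The operation is idempotent on its own output.
#'
#' @param x a `raman_spectrum`.
#' @param window odd rolling-window width (>= 3).
#' @param k_sigma replacement threshold in robust sigmas.
#' @param rel_frac additional spike criterion: the excursion above the
#'   rolling median must also exceed this fraction of the value itself. A
#'   hot pixel exceeds its rolling median by its full height, while the
#'   center of a resolved Raman line (FWHM >= window samples) exceeds it
#'   by a small fraction only, so genuine lines survive at any
#'   signal-to-noise ratio.
#' @return the cleaned `raman_spectrum` with a logical attribute `mask`
#'   (TRUE where a value was replaced).
#' @export
remove_hot_pixels <- function(x, window = 5, k_sigma = 8, rel_frac = 0.3) {
  if (window < 3 || window %% 2 == 0) abort("window must be odd and >= 3")
  med <- stats::runmed(x$intensity, window, endrule = "median")
  resid <- x$intensity - med
  sigma <- stats::mad(resid)
  if (sigma == 0) sigma <- stats::sd(resid)
  mask <- if (is.na(sigma) || sigma == 0) {
    rep(FALSE, length(resid))
  } else {
    resid > k_sigma * sigma & resid > rel_frac * pmax(x$intensity, 0)
  }
  y <- x$intensity
  y[mask] <- med[mask]
  out <- spectrum_like(x, intensity = y)
  attr(out, "mask") <- mask
  out
}

#' Estimate the signal-to-noise ratio of a calibrated spectrum
#'
#' The instrument's standard SNR figure: the baseline-subtracted amplitude
#' of the 1001 cm^-1 polystyrene line divided by the RMS of the detrended
#' residual in the signal-free 1700-2100 cm^-1 window. The peak baseline is
#' interpolated linearly between the medians of two flanking bands; the
#' noise window is detrended with a 2nd-order polynomial before taking the
#' RMS (it may sit on residual fluorescence).
#'
#' @param x a `raman_spectrum` on a Raman-shift axis covering both regions.
#' @param peak_at signal line position, cm^-1.
#' @param noise_window two-element range in cm^-1.
#' @param flank half-widths (inner, outer) in cm^-1 of the baseline bands
#'   flanking the peak.
#' @return a one-row tibble of class `snr_estimate`: `signal`, `noise`,
#'   `snr`, `peak_at`, plus the windows used. With zero noise, `snr` is
#'   `Inf`.
#' @export
estimate_snr <- function(x, peak_at = 1001, noise_window = c(1700, 2100),
                         flank = c(15, 30)) {
  if (axis_kind(x) != "raman_shift_cm1") {
    abort("SNR estimation needs a calibrated Raman-shift axis")
  }
  if (min(x$axis) > noise_window[1] || max(x$axis) < noise_window[2]) {
    abort("noise window outside the axis")
  }
  i_peak <- which.min(abs(x$axis - peak_at))
  left <- x$intensity[x$axis >= peak_at - flank[2] & x$axis <= peak_at - flank[1]]
  right <- x$intensity[x$axis >= peak_at + flank[1] & x$axis <= peak_at + flank[2]]
  if (!length(left) || !length(right)) abort("baseline flanks outside the axis")
  base <- (stats::median(left) + stats::median(right)) / 2
  signal <- x$intensity[i_peak] - base
  nw <- x$axis >= noise_window[1] & x$axis <= noise_window[2]
  a <- x$axis[nw]
  y <- x$intensity[nw]
  resid <- stats::residuals(stats::lm(y ~ stats::poly(a, 2)))
  noise <- rms(resid)
  out <- tibble::tibble(signal = signal, noise = noise,
                        snr = if (noise > 0) signal / noise else Inf,
                        peak_at = peak_at,
                        noise_lo = noise_window[1], noise_hi = noise_window[2])
  class(out) <- c("snr_estimate", class(out))
  out
}

#' Row-compression SNR experiment
#'
#' Quantifies the gain from concentrating the Raman band into a single
#' sensor row instead of spreading it over `n_rows` rows that are then
#' summed. An identical total expected signal profile is distributed over 1
#' or `n_rows` rows, per-pixel Gaussian dark noise (and optionally Poisson
#' shot noise) is added, the rows are summed, and the SNR is estimated with
#' [estimate_snr()]. In the dark-noise-dominated regime the ratio approaches
#' `sqrt(n_rows)`; with pure shot noise it approaches 1.
#'
#' @param profile numeric vector: total expected band counts per column.
#' @param axis_cm1 calibrated Raman-shift axis for the columns.
#' @param n_rows number of rows the signal is spread over in the comparison
#'   configuration.
#' @param dark_noise_sd per-pixel dark noise std (counts).
#' @param shot_noise add Poisson shot noise as well?
#' @param n_reps number of replicate frames per configuration.
#' @param seed integer seed.
#' @param ... further arguments passed to [estimate_snr()].
#' @return a list with `snr_1` and `snr_n` (mean SNR per configuration),
#'   `ratio = snr_1/snr_n`, and the per-replicate tibble `reps`.
#' @export
row_compression_snr <- function(profile, axis_cm1, n_rows = 20,
                                dark_noise_sd = 12, shot_noise = FALSE,
                                n_reps = 100, seed = 1, ...) {
  stopifnot(n_rows >= 1, n_reps >= 1, length(profile) == length(axis_cm1))
  one_config <- function(k) {
    per_row <- profile / k
    vapply(seq_len(n_reps), function(r) {
      summed <- numeric(length(profile))
      for (row in seq_len(k)) {
        v <- if (shot_noise) stats::rpois(length(per_row), per_row) else per_row
        summed <- summed + v +
          stats::rnorm(length(per_row), 0, dark_noise_sd)
      }
      estimate_snr(raman_spectrum(axis_cm1, summed), ...)$snr
    }, numeric(1))
  }
  with_seed(seed, {
    snr1 <- one_config(1L)
    snrn <- if (n_rows == 1L) snr1 else one_config(n_rows)
    list(snr_1 = mean(snr1), snr_n = mean(snrn),
         ratio = mean(snr1) / mean(snrn),
         reps = tibble::tibble(rep = seq_len(n_reps), snr_1 = snr1,
                               snr_n = snrn))
  })
}
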