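test_that("reference peak fitting recovers noiseless centers to 0.05 pixel", {
  cfg <- linear_instrument()
  true_nm <- 785.2
  fr <- render_frame(cfg, laser_state(true_nm), polystyrene_sample(),
                     noise = FALSE)
  ref <- extract_channel(fr, "reference", cfg$optics)
  fits <- fit_reference_peaks(ref, cfg$ref_lines, cfg$optics, 785)
  ok <- fits[fits$success, ]
  expect_gte(nrow(ok), 5)
  pred <- col_of_wavelength(
    cfg$optics, shift_to_wavelength(true_nm, ok$line_cm1), cfg$sensor$cols)
  expect_lt(max(abs(ok$center_px - pred)), 0.05)

  zeros <- raman_spectrum(seq_len(cfg$sensor$cols),
                          rep(0, cfg$sensor$cols), kind = "pixel")
  expect_error(fit_reference_peaks(zeros, cfg$ref_lines, cfg$optics, 785),
               "fewer than 3")
})

test_that("laser wavenumber recovery: drift, equivariance, robustness", {
  cfg <- linear_instrument()
  fr <- render_frame(cfg, laser_state(785.15), polystyrene_sample(),
                     noise = FALSE)
  ref <- extract_channel(fr, "reference", cfg$optics)
  fits <- fit_reference_peaks(ref, cfg$ref_lines, cfg$optics, 785)
  cal <- estimate_laser_wavenumber(fits)
  expect_equal(cal$laser_nm, 785.15, tolerance = 0.01 / 785)

  # all peaks consistently +4 cm^-1 late (wavelengths red by 4 cm^-1)
  # move the laser estimate by exactly -4 cm^-1
  shifted <- fits
  nu_shift <- 4 # cm^-1
  shifted$center_nm <- 1e7 / (1e7 / fits$center_nm - nu_shift)
  cal2 <- estimate_laser_wavenumber(shifted)
  expect_equal(cal2$laser_nu_cm1 - cal$laser_nu_cm1, -nu_shift,
               tolerance = 1e-9)

  # one corrupted peak among six is rejected by the MAD pass
  bad <- fits[fits$success, ][1:6, ]
  cal3 <- estimate_laser_wavenumber(bad)
  bad$center_nm[3] <- bad$center_nm[3] + 0.3
  cal4 <- estimate_laser_wavenumber(bad)
  expect_lt(abs(cal4$laser_nu_cm1 - cal3$laser_nu_cm1), 0.1)

  # Monte-Carlo: centers stay within 0.2 px at reference SNR ~ 100
  cfg_lo <- linear_instrument(ref_amplitude = 2.5e4)
  devs <- vapply(1:25, function(i) {
    frn <- render_frame(cfg_lo, laser_state(785.15),
                        polystyrene_sample(), seed = i)
    f <- fit_reference_peaks(extract_channel(frn, "reference", cfg_lo$optics),
                             cfg_lo$ref_lines, cfg_lo$optics, 785)
    f <- f[f$success & f$line_cm1 == 1001.4, ]
    f$center_px
  }, numeric(1))
  pred <- col_of_wavelength(cfg_lo$optics,
                            shift_to_wavelength(785.15, 1001.4))
  expect_lt(max(abs(devs - pred)), 0.2)
})

test_that("calibration pins Raman features against laser drift", {
  # parameter recovery across a warm-up sequence
  sim <- simulate_and_calibrate(12, sample = polystyrene_sample(),
                                drift_nm = 0.3, tau_s = 60, seed = 4)
  res <- sim$result
  expect_true(all(res$log$ok))
  err_nm <- res$log$laser_nm - sim$states$center_nm
  err_cm1 <- 1e7 / res$log$laser_nm - 1e7 / sim$states$center_nm
  expect_lt(max(abs(err_cm1)), 1.5)

  # polystyrene measured in the MAIN channel: strongest fingerprint peak
  # lands at 1001 cm^-1 whatever the laser did
  centers <- vapply(res$spectra, function(s) {
    fit_line_fwhm(s, 1001.4, "gaussian", window = 12)$center
  }, numeric(1))
  expect_true(all(round(centers) == 1001))
  expect_lt(max(abs(centers - 1001.4)), 2)

  # identity: with a truth-calibration the axis is exact
  cfg <- linear_instrument()
  st <- laser_state(785)
  fr <- render_frame(cfg, st, polystyrene_sample(), noise = FALSE)
  cal0 <- structure(list(laser_nu_cm1 = 1e7 / 785, laser_nm = 785,
                         residuals_cm1 = numeric(0), n_peaks = 0L,
                         intensity_scale = NA_real_, acquisition = "t"),
                    class = "calibration_result")
  main <- extract_channel(fr, "main", cfg$optics)
  spec <- calibrate_shift_axis(main, cal0, cfg$optics)
  truth <- 1e7 / 785 - 1e7 / wavelength_of_col(cfg$optics, main$axis)
  expect_true(min(spec$axis) >= min(truth) - 1e-6 &&
                max(spec$axis) <= max(truth) + 1e-6)
  expect_equal(diff(spec$axis)[1], 0.5)
})

test_that("intensity normalization cancels simulated power fluctuation", {
  cfg <- linear_instrument()
  powers <- c(1.0, 0.9, 1.1)
  frames <- lapply(seq_along(powers), function(i) {
    render_frame(cfg, laser_state(785.05, power = powers[i]),
                 polystyrene_sample(), seed = 40 + i)
  })
  res <- run_pipeline(pipeline_config(cfg), frames)
  expect_true(all(res$log$ok))
  areas <- vapply(res$spectra, window_area, numeric(1), center = 1001.4,
                  halfwidth = 15)
  expect_lt((max(areas) - min(areas)) / mean(areas), 0.01)

  # same-frame baseline gives scale 1 exactly
  ref_cm <- calibrate_shift_axis(
    extract_channel(frames[[1]], "reference", cfg$optics),
    res$calibrations[[1]], cfg$optics)
  a <- ref_peak_area(ref_cm)
  norm <- normalize_intensity(res$spectra[[1]], ref_cm, a)
  expect_equal(attr(norm, "intensity_scale"), 1)

  # scale recovery: power 0.8 -> scale 1.25
  scales <- vapply(1:15, function(i) {
    f1 <- render_frame(cfg, laser_state(785.05, power = 1),
                       polystyrene_sample(), seed = 100 + i)
    f2 <- render_frame(cfg, laser_state(785.05, power = 0.8),
                       polystyrene_sample(), seed = 200 + i)
    r <- run_pipeline(pipeline_config(cfg), list(f1, f2))
    r$log$intensity_scale[2]
  }, numeric(1))
  expect_equal(mean(scales), 1.25, tolerance = 0.01)
  expect_error(normalize_intensity(res$spectra[[1]], ref_cm, -1), "positive")
})

test_that("blackbody response correction is self-consistent and invertible", {
  lam <- seq(800, 960, by = 0.5)
  # flat instrument: measured lamp = Planck curve itself
  lamp_flat <- raman_spectrum(lam, planck_radiance(3000, lam),
                              kind = "wavelength_nm")
  curve <- build_response_curve(lamp_flat)
  expect_equal(curve$response, rep(1, length(lam)))
  flatten <- apply_response(lamp_flat, curve)
  expect_equal(flatten$intensity, lamp_flat$intensity)

  # synthetic linear response 1 -> 0.5 across the band recovered within 1%
  resp_true <- seq(1, 0.5, length.out = length(lam))
  lamp_meas <- raman_spectrum(lam, planck_radiance(3000, lam) * resp_true,
                              kind = "wavelength_nm")
  curve2 <- build_response_curve(lamp_meas)
  expect_equal(curve2$response, resp_true / max(resp_true), tolerance = 0.01)

  # apply then invert is the identity
  s <- raman_spectrum(seq(400, 2300, 0.5),
                      runif(3801, 10, 100))
  corrected <- apply_response(s, curve2, laser_nm = 785)
  back <- apply_response(corrected, curve2, laser_nm = 785, invert = TRUE)
  expect_equal(back$intensity, s$intensity, tolerance = 1e-9)

  expect_error(build_response_curve(
    raman_spectrum(lam, c(0, rep(1, length(lam) - 1)),
                   kind = "wavelength_nm")), "positive")
})

test_that("drift averaging suppresses static QE noise as sqrt(M)", {
  cfg <- linear_instrument()
  qe <- make_qe_map(cfg$sensor, 0.003, seed = 21)
  # smooth fluorescence only; laser steps across M distinct pixel alignments
  fluor <- function(lam) 2e4 * exp(-((lam - 870) / 60)^2)
  smp <- list(lines = NULL, amplitude = 0, fluorescence = fluor)
  M <- 10
  px_nm <- 0.08
  calibrate_one <- function(lam0, seed) {
    fr <- render_frame(cfg, laser_state(lam0), smp, seed = seed,
                       qe_map = qe, noise = FALSE)
    cal <- structure(list(laser_nu_cm1 = 1e7 / lam0, laser_nm = lam0,
                          residuals_cm1 = numeric(0), n_peaks = 0L,
                          intensity_scale = NA_real_, acquisition = "q"),
                     class = "calibration_result")
    calibrate_shift_axis(extract_channel(fr, "main", cfg$optics), cal,
                         cfg$optics, grid = seq(600, 2100, by = 0.5))
  }
  shifted <- lapply(seq_len(M) - 1, function(k) {
    calibrate_one(785 + k * px_nm, seed = 50 + k)
  })
  avg_shift <- drift_average(shifted)
  # negative control: no drift, the same alignment every time -> the QE
  # pattern is identical in every spectrum and does not average out
  static <- lapply(seq_len(M), function(k) calibrate_one(785, seed = 50))
  expect_warning(avg_static <- drift_average(
    static, calibrations = rep(list(structure(
      list(laser_nu_cm1 = 1e7 / 785), class = "calibration_result")), M)),
    "ineffective")
  expect_equal(avg_static$mean$intensity, static[[1]]$intensity)
  expect_equal(avg_static$report$reduction, 1, tolerance = 0.05)
  # drifted alignments decorrelate the static pattern and suppress it
  expect_gt(avg_shift$report$reduction, 2)
  # monotone improvement with the number of distinct alignments
  red <- vapply(c(2, 5, 10), function(m) {
    drift_average(shifted[1:m])$report$reduction
  }, numeric(1))
  expect_true(all(diff(red) > 0))

  # independence oracle on the sqrt(M) law: with spectra whose QE-like
  # noise realizations are independent, averaging M of them cuts the
  # high-frequency metric by sqrt(M) exactly
  set.seed(77)
  ax <- seq(600, 2100, by = 0.5)
  smooth_bg <- 1e4 * exp(-((ax - 1300) / 500)^2)
  iid <- lapply(seq_len(M), function(i) {
    raman_spectrum(ax, smooth_bg * (1 + rnorm(length(ax), 0, 0.003)))
  })
  avg_iid <- drift_average(iid)
  expect_equal(avg_iid$report$reduction, sqrt(M), tolerance = 0.25)
})
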