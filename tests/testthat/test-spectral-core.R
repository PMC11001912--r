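test_that("Raman shift / wavelength conversion matches the closed form and inverts", {
  expect_equal(shift_to_wavelength(785, 0), 785)
  expect_equal(shift_to_wavelength(675, 2700), 1e7 / (1e7 / 675 - 2700))
  expect_equal(shift_to_wavelength(675, 2700), 825.4356, tolerance = 1e-6)
  # the 675 nm laser must place the high-frequency band inside the sensor
  expect_gt(shift_to_wavelength(675, 2700), 800)
  expect_lt(shift_to_wavelength(675, 4000), 960)
  expect_equal(shift_to_wavelength(785, 2300), 957.9596, tolerance = 1e-6)
  expect_equal(wavelength_to_shift(785, 785), 0)
  expect_equal(wavelength_to_shift(785, 957.9596), 2300, tolerance = 1e-4)

  set.seed(42)
  lam <- runif(100, 800, 960)
  back <- shift_to_wavelength(785, wavelength_to_shift(785, lam))
  expect_equal(back, lam, tolerance = 1e-9)

  expect_error(shift_to_wavelength(785, 13000), "non-positive")
  expect_error(shift_to_wavelength(-1, 100), "positive")
})

test_that("synthesized profiles have the analytic FWHM and area", {
  grid <- seq(1200, 1460, by = 0.1)
  diam <- line_list("diamond", data.frame(
    center_cm1 = 1332, rel_intensity = 1, fwhm_cm1 = 1.8,
    shape = "lorentzian"))
  s <- synthesize_spectrum(diam, grid)
  fit <- fit_line_fwhm(s, 1332, "lorentzian", window = 30)
  expect_equal(fit$fwhm, 1.8, tolerance = 0.01)
  expect_equal(fit$center, 1332, tolerance = 0.01)

  # unit-area Gaussian on a fine grid integrates to 1
  g <- line_list("x", data.frame(center_cm1 = 1000, rel_intensity = 1,
                                 fwhm_cm1 = 10, shape = "gaussian"))
  ax <- seq(900, 1100, by = 1) # step = 0.1 FWHM
  sg <- synthesize_spectrum(g, ax)
  expect_equal(pracma::trapz(sg$axis, sg$intensity), 1, tolerance = 1e-3)

  # zero-intensity lines give a zero spectrum
  z <- line_list("x", data.frame(center_cm1 = 1000, rel_intensity = 0,
                                 fwhm_cm1 = 10, shape = "gaussian"))
  expect_equal(synthesize_spectrum(z, ax)$intensity, rep(0, length(ax)))

  # FWHM matches the analytic width within a grid step for all families
  fine <- seq(800, 1200, by = 0.2)
  for (sh in c("gaussian", "lorentzian", "voigt")) {
    ll <- line_list("x", data.frame(
      center_cm1 = 1000, rel_intensity = 1, fwhm_cm1 = 8, shape = sh,
      gauss_fwhm = if (sh == "voigt") 6 else NA,
      lorentz_fwhm = if (sh == "voigt") 4 else NA))
    sp <- synthesize_spectrum(ll, fine)
    expect_equal(reframan:::profile_fwhm(sp$axis, sp$intensity),
                 ll$fwhm_cm1[1], tolerance = 0.2)
  }

  # line outside the axis span warns and is skipped
  far <- line_list("x", data.frame(center_cm1 = 3000, rel_intensity = 1,
                                   fwhm_cm1 = 10, shape = "gaussian"))
  expect_warning(s0 <- synthesize_spectrum(far, ax), "outside")
  expect_equal(s0$intensity, rep(0, length(ax)))
})

test_that("Voigt FWHM follows the Olivero-Longbothum approximation", {
  expect_equal(voigt_fwhm(6, 0), 6)
  expect_equal(voigt_fwhm(0, 4), 4, tolerance = 1e-3)
  expect_equal(voigt_fwhm(6, 4), 0.5346 * 4 + sqrt(0.2166 * 16 + 36))
})

test_that("Planck radiance peaks near the Wien wavelength and rises over the band", {
  lam <- seq(300, 3000, by = 1)
  b <- planck_radiance(3000, lam)
  expect_equal(lam[which.max(b)], 2.898e6 / 3000, tolerance = 0.005)
  band <- planck_radiance(3000, seq(800, 960, by = 1))
  expect_true(all(diff(band) > 0)) # peak lies above the sensor band
  expect_true(all(b > 0))
  expect_equal(length(which(diff(sign(diff(b))) < 0)), 1) # single maximum
  expect_equal(planck_radiance(3000, 850) / planck_radiance(3000, 850), 1)
})

test_that("resampling is exact on linear data and conserves peak area", {
  ramp <- raman_spectrum(seq(0, 100, by = 1), seq(0, 100, by = 1) * 2 + 5)
  tgt <- sort(runif(50, 0, 100))
  rs <- resample_spectrum(ramp, tgt)
  expect_equal(rs$intensity, tgt * 2 + 5, tolerance = 1e-12)

  same <- resample_spectrum(ramp, ramp$axis)
  expect_equal(same$intensity, ramp$intensity)

  # peak area preserved within 0.5% for step <= FWHM/5
  fine <- seq(950, 1050, by = 0.1)
  pk <- raman_spectrum(fine, dnorm(fine, 1000, 10 / 2.355))
  coarse <- resample_spectrum(pk, seq(950, 1050, by = 2))
  a0 <- pracma::trapz(pk$axis, pk$intensity)
  a1 <- pracma::trapz(coarse$axis, coarse$intensity)
  expect_equal(a1, a0, tolerance = 5e-3)

  expect_error(resample_spectrum(ramp, seq(500, 600)), "overlap")
  # out-of-support points are filled and masked
  ext <- resample_spectrum(ramp, seq(-10, 10, by = 1), fill = -1)
  expect_true(all(attr(ext, "mask")[1:10]))
  expect_equal(ext$intensity[1:10], rep(-1, 10))
})

test_that("spectrum and line-list constructors enforce their invariants", {
  expect_error(raman_spectrum(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(raman_spectrum(1:3, c(0, NA, 0)), "finite")
  expect_error(raman_spectrum(c(1.5, 2.5), c(0, 0), kind = "pixel"),
               "integer")
  expect_error(line_list("x", data.frame(center_cm1 = c(1, 1),
                                         rel_intensity = 1, fwhm_cm1 = 1,
                                         shape = "gaussian")), "unique")
  ps <- builtin_linelist("polystyrene")
  expect_true(all(diff(ps$center_cm1) > 0))
  expect_s3_class(ps, "line_list")
})

test_that("spectra and line lists round-trip through their file formats", {
  s <- raman_spectrum(seq(400, 500, 0.5), runif(201), channel = "reference",
                      exposure_s = 0.25, acquisition = "a7")
  f <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(s, f)
  s2 <- read_spectrum(f)
  expect_equal(s2$axis, s$axis)
  expect_equal(s2$intensity, s$intensity, tolerance = 1e-9)
  expect_equal(attr(s2, "channel"), "reference")
  expect_equal(attr(s2, "exposure_s"), 0.25)

  ll <- builtin_linelist("toluene")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_linelist(ll, f2)
  ll2 <- read_linelist(f2)
  expect_equal(ll2$center_cm1, ll$center_cm1)
  expect_equal(attr(ll2, "material"), "toluene")
})
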