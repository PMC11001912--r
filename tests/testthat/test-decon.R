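test_that("hop-kernel estimation: identity, recovery, and degenerate input", {
  cfg <- linear_instrument()
  clean <- extract_channel(render_frame(cfg, laser_state(785.1),
                                        polystyrene_sample(),
                                        noise = FALSE),
                           "reference", cfg$optics)
  k0 <- estimate_hop_kernel(clean, clean)
  expect_equal(k0$offsets, 0L)
  expect_equal(k0$weights, 1)

  # two-spike blur, weights 0.7/0.3 at offsets 0/+3, moderate noise
  shift3 <- c(rep(0, 3), utils::head(clean$intensity, -3))
  set.seed(2)
  obs <- raman_spectrum(clean$axis,
                        0.7 * clean$intensity + 0.3 * shift3 +
                          rnorm(nrow(clean), 0, 15), kind = "pixel")
  k <- estimate_hop_kernel(obs, clean)
  w <- setNames(rep(0, 15), -7:7)
  w[as.character(k$offsets)] <- k$weights
  expect_equal(unname(w["0"]), 0.7, tolerance = 0.05)
  expect_equal(unname(w["3"]), 0.3, tolerance = 0.05)
  expect_lt(sum(w[setdiff(names(w), c("0", "3"))]), 0.1)

  set.seed(5)
  noise_only <- raman_spectrum(clean$axis, rnorm(nrow(clean), 100, 10),
                               kind = "pixel")
  expect_error(estimate_hop_kernel(noise_only, clean), "unreliable")
})

test_that("Richardson-Lucy deconvolution restores hop-blurred spectra and conserves flux", {
  cfg <- linear_instrument()
  m_clean <- extract_channel(render_frame(cfg, laser_state(785.1),
                                          polypropylene_sample(),
                                          noise = FALSE),
                             "main", cfg$optics)
  k <- broadening_kernel(c(0, 3), c(0.7, 0.3))
  blurred <- raman_spectrum(
    m_clean$axis,
    0.7 * m_clean$intensity +
      0.3 * c(rep(0, 3), utils::head(m_clean$intensity, -3)),
    kind = "pixel")
  dec <- deconvolve_with_kernel(blurred, k, iterations = 80)

  i <- which.max(m_clean$intensity)
  fc <- fit_line_fwhm(m_clean, m_clean$axis[i], "gaussian", window = 15)
  fb <- fit_line_fwhm(blurred, m_clean$axis[i], "gaussian", window = 15)
  fd <- fit_line_fwhm(dec, m_clean$axis[i], "gaussian", window = 15)
  expect_gt(fb$fwhm, fc$fwhm) # the hop visibly broadens
  expect_equal(fd$fwhm, fc$fwhm, tolerance = 0.1)
  expect_equal(max(dec$intensity), max(m_clean$intensity), tolerance = 0.05)
  # flux conserved within 0.1%
  expect_equal(sum(dec$intensity), sum(blurred$intensity), tolerance = 1e-3)
  expect_true(all(dec$intensity >= 0))

  # delta kernel is the identity
  delta <- broadening_kernel(0, 1)
  expect_equal(deconvolve_with_kernel(blurred, delta)$intensity,
               blurred$intensity)
})

test_that("kernel correction reduces peak position and amplitude errors on simulator output", {
  cfg <- linear_instrument()
  clean_ref <- extract_channel(render_frame(cfg, laser_state(785.1),
                                            polystyrene_sample(),
                                            noise = FALSE),
                               "reference", cfg$optics)
  m_clean <- extract_channel(render_frame(cfg, laser_state(785.1),
                                          polypropylene_sample(),
                                          noise = FALSE),
                             "main", cfg$optics)
  i_peak <- which.max(m_clean$intensity)
  amp_errs <- vapply(1:12, function(s) {
    set.seed(s)
    w <- runif(1, 0.55, 0.8)
    off <- sample(2:4, 1)
    blur <- function(v) w * v + (1 - w) * c(rep(0, off),
                                            utils::head(v, -off))
    obs_ref <- raman_spectrum(clean_ref$axis,
                              blur(clean_ref$intensity) +
                                rnorm(nrow(clean_ref), 0, 10),
                              kind = "pixel")
    obs_main <- raman_spectrum(m_clean$axis,
                               blur(m_clean$intensity) +
                                 rnorm(nrow(m_clean), 0, 10),
                               kind = "pixel")
    k <- estimate_hop_kernel(obs_ref, clean_ref)
    dec <- deconvolve_with_kernel(obs_main, k, iterations = 60)
    c(before = abs(max(obs_main$intensity) - max(m_clean$intensity)),
      after = abs(max(dec$intensity) - max(m_clean$intensity)))
  }, numeric(2))
  expect_lt(mean(amp_errs["after", ]), mean(amp_errs["before", ]))
})

test_that("apparatus function estimation deconvolves the natural diamond linewidth", {
  g <- standard_shift_grid(1150, 1520)
  off <- seq(-20, 20, by = 0.5)
  app_true <- gauss_profile(off, 0, 6.0) * 0.5
  meas <- reframan:::conv_same(lorentz_profile(g, 1332.5, 1.8), app_true)
  app <- estimate_apparatus_function(raman_spectrum(g, meas * 1e4))
  expect_equal(attr(app, "fwhm_cm1"), 6.0, tolerance = 0.2 / 6)
  expect_equal(pracma::trapz(app$offset_cm1, app$value), 1, tolerance = 1e-6)
  expect_true(all(app$value >= 0))

  # measured == natural line exactly -> near-delta apparatus
  nat <- raman_spectrum(g, lorentz_profile(g, 1332.5, 1.8) * 1e4)
  app0 <- estimate_apparatus_function(nat)
  expect_lte(attr(app0, "fwhm_cm1"), 1.0) # <= 2 grid steps

  # 1% noise: width stable within 5% over repeats
  fwhms <- vapply(1:20, function(s) {
    set.seed(s)
    noisy <- raman_spectrum(g, meas * 1e4 +
                              rnorm(length(g), 0, max(meas * 1e4) / 100))
    attr(estimate_apparatus_function(noisy), "fwhm_cm1")
  }, numeric(1))
  expect_lt(stats::sd(fwhms) / mean(fwhms), 0.05)
  expect_error(estimate_apparatus_function(
    raman_spectrum(g, rep(1, length(g)))), "no dominant line")
})

test_that("deblurring restores narrow lines and resolves close doublets", {
  g <- standard_shift_grid(1150, 1520)
  off <- seq(-30, 30, by = 0.5)
  app <- apparatus_function(off, gauss_profile(off, 0, 10))
  narrow <- lorentz_profile(g, 1332.5, 1.8)
  blurred <- reframan:::conv_same(narrow, app$value * 0.5)
  set.seed(3)
  y <- blurred * 3000 + rnorm(length(g), 0, max(blurred * 3000) / 300)
  sp <- raman_spectrum(g, pmax(y, 0))
  db <- deblur(sp, app, iterations = 60)
  expect_lte(fit_line_fwhm(db, 1332.5, "voigt", window = 20)$fwhm, 7)
  expect_equal(sum(db$intensity), sum(sp$intensity), tolerance = 1e-3)

  # delta apparatus is the identity
  dapp <- apparatus_function(off, c(rep(0, 60), 1, rep(0, 60)))
  expect_equal(deblur(sp, dapp)$intensity, sp$intensity, tolerance = 1e-9)

  # an 8 cm^-1 doublet unresolved before deblurring gains a local minimum
  doublet <- lorentz_profile(g, 1330, 2) + lorentz_profile(g, 1338, 2)
  blur2 <- raman_spectrum(g, reframan:::conv_same(doublet, app$value * 0.5) * 1e4)
  between <- g > 1331 & g < 1337
  local_min <- function(v) any(diff(sign(diff(v))) > 0)
  expect_false(local_min(blur2$intensity[between]))
  db2 <- deblur(blur2, app, iterations = 200, tol = 0)
  expect_true(local_min(db2$intensity[between]))
})

test_that("Voigt fits recover synthesized widths; quadrature resolution formula", {
  g <- seq(900, 1100, by = 0.25)
  s <- raman_spectrum(g, 500 * pseudo_voigt_profile(g, 1001, 4, 3) + 2)
  fit <- fit_line_fwhm(s, 1001, "voigt", window = 40)
  expect_equal(fit$gauss_fwhm, 4, tolerance = 0.02)
  expect_equal(fit$lorentz_fwhm, 3, tolerance = 0.02)
  expect_equal(fit$fwhm, voigt_fwhm(4, 3), tolerance = 0.02)

  expect_equal(resolution_from_fwhm(7.4, 3.35), 6.6, tolerance = 0.01)
  expect_equal(resolution_from_fwhm(5, 0), 5)
  expect_error(resolution_from_fwhm(3, 4), ">=")
})

test_that("transform-domain convolution agrees with direct summation", {
  set.seed(8)
  x <- runif(256)
  k <- dnorm(seq(-10, 10), 0, 3)
  k <- k / sum(k)
  expect_equal(reframan:::fft_conv_same(x, k), reframan:::conv_same(x, k), tolerance = 1e-9)
})
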