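#' Laser model
#'
#' Parameterizes a non-stabilized Fabry-Perot diode laser: nominal emission
#' wavelength, linewidth, maximum power, an exponential-approach thermal
#' warm-up drift, discrete mode hops, and AR(1) relative power fluctuation.
#'
#' @param nominal_nm nominal (cold) central wavelength in nm; the instrument
#'   uses 785 nm for the fingerprint range and 675 nm for the high-frequency
#'   range.
#' @param linewidth_nm emission linewidth FWHM in nm (default 0.2).
#' @param max_power_mW maximum optical power (default 200).
#' @param drift_nm total thermal wavelength drift at full warm-up in nm.
#' @param drift_tau_s thermal time constant in s: wavelength follows
#'   `nominal + drift_nm * (1 - exp(-t/tau))`.
#' @param hop_spacing_nm mode-hop spacing (one cavity free spectral range).
#' @param hop_prob per-frame probability of a mode hop during the exposure.
#' @param power_rel_sd stationary relative standard deviation of the frame
#'   power around 1.0.
#' @param power_ar1 lag-one correlation of the power fluctuation.
#' @return a list of class `laser_model`.
#' @export
laser_model <- function(nominal_nm = 785, linewidth_nm = 0.2,
                        max_power_mW = 200, drift_nm = 0.3, drift_tau_s = 60,
                        hop_spacing_nm = 0.1, hop_prob = 0,
                        power_rel_sd = 0, power_ar1 = 0.9) {
  stopifnot(nominal_nm > 0, linewidth_nm > 0, max_power_mW > 0,
            drift_tau_s > 0, hop_spacing_nm > 0,
            hop_prob >= 0, hop_prob <= 1, power_rel_sd >= 0,
            power_ar1 >= 0, power_ar1 < 1)
  structure(list(nominal_nm = nominal_nm, linewidth_nm = linewidth_nm,
                 max_power_mW = max_power_mW, drift_nm = drift_nm,
                 drift_tau_s = drift_tau_s, hop_spacing_nm = hop_spacing_nm,
                 hop_prob = hop_prob, power_rel_sd = power_rel_sd,
                 power_ar1 = power_ar1),
            class = "laser_model")
}

#' Laser emission state for one exposure
#'
#' When a mode hop occurs within one exposure, the collected spectrum is a
#' weighted superposition of the spectra at the pre- and post-hop
#' wavelengths; the state therefore holds one or more emission components
#' with normalized weights, plus the relative power for the frame.
#'
#' @param wavelength_nm emission wavelength(s) in nm.
#' @param weight non-negative weights, normalized to sum 1.
#' @param power relative optical power (1 = nominal).
#' @return a list of class `laser_state`.
#' @export
laser_state <- function(wavelength_nm, weight = rep(1, length(wavelength_nm)),
                        power = 1) {
  stopifnot(length(wavelength_nm) >= 1,
            length(weight) == length(wavelength_nm),
            all(weight >= 0), sum(weight) > 0, power > 0)
  structure(list(components = tibble::tibble(wavelength_nm = wavelength_nm,
                                             weight = weight / sum(weight)),
                 power = power),
            class = "laser_state")
}

#' Simulate a laser warm-up sequence
#'
#' Generates per-frame [laser_state()]s under the thermal drift model
#' `lambda(t) = nominal + drift * (1 - exp(-t/tau))`, with accumulated
#' discrete mode hops of +-`hop_spacing_nm` and AR(1) power fluctuation
#' around 1. A hop that falls inside an exposure yields a two-component
#' state with a uniform random split of the exposure time (at most 3
#' components per exposure).
#'
#' @param model a [laser_model()].
#' @param n_frames number of frames (>= 1).
#' @param frame_period_s time between frame starts in s.
#' @param seed integer seed; identical seeds give identical sequences.
#' @return a tibble with columns `frame`, `t_s`, `center_nm` (weighted mean
#'   emission wavelength), `power`, `n_hops`, and a list-column `state` of
#'   `laser_state` objects.
#' @export
simulate_laser_sequence <- function(model, n_frames, frame_period_s = 1,
                                    seed = 1) {
  stopifnot(inherits(model, "laser_model"), n_frames >= 1)
  with_seed(seed, {
    t_s <- (seq_len(n_frames) - 1) * frame_period_s
    base <- model$nominal_nm +
      model$drift_nm * (1 - exp(-t_s / model$drift_tau_s))
    hop_here <- stats::rbinom(n_frames, 1, model$hop_prob)
    hop_sign <- sample(c(-1, 1), n_frames, replace = TRUE)
    hop_frac <- stats::runif(n_frames, 0.2, 0.8)
    power <- numeric(n_frames)
    p <- 1
    innov_sd <- model$power_rel_sd * sqrt(1 - model$power_ar1^2)
    for (i in seq_len(n_frames)) {
      p <- 1 + model$power_ar1 * (p - 1) + stats::rnorm(1, 0, innov_sd)
      power[i] <- max(p, 0.01)
    }
    hop_offset <- 0
    states <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      lam <- base[i] + hop_offset
      if (hop_here[i] == 1) {
        new_offset <- hop_offset + hop_sign[i] * model$hop_spacing_nm
        states[[i]] <- laser_state(
          c(lam, base[i] + new_offset),
          weight = c(hop_frac[i], 1 - hop_frac[i]),
          power = power[i])
        hop_offset <- new_offset
      } else {
        states[[i]] <- laser_state(lam, power = power[i])
      }
    }
    center <- vapply(states, function(s) {
      sum(s$components$wavelength_nm * s$components$weight)
    }, numeric(1))
    tibble::tibble(frame = seq_len(n_frames), t_s = t_s, center_nm = center,
                   power = power, n_hops = hop_here, state = states)
  })
}

#' Sensor model
#'
#' Non-cooled NIR-enhanced imaging CMOS sensor: 64 x 2000 binned pixels of
#' 4 um pitch, 16-bit counts, Gaussian dark+read noise, optional hot pixels,
#' static per-pixel multiplicative quantum-efficiency (QE) variation, and a
#' wavelength-dependent QE falling from 60% at 840 nm to 40% at 940 nm.
#'
#' @param rows,cols sensor geometry (binned pixels).
#' @param pitch_um binned pixel pitch in um.
#' @param dark_noise_sd dark+read noise standard deviation, counts per pixel
#'   for a 1 s exposure (scales with sqrt of exposure).
#' @param saturation full-scale count (16-bit).
#' @param hot_pixel_frac fraction of pixels rendered hot in each frame.
#' @param qe_sigma relative standard deviation of the static per-pixel QE
#'   gain variation (0 to 0.01; real sensors show 0.001-0.005).
#' @param qe_points two-column matrix (wavelength nm, QE) through which the
#'   spectral QE curve is linearly interpolated.
#' @return a list of class `sensor_model`.
#' @export
sensor_model <- function(rows = 64, cols = 2000, pitch_um = 4,
                         dark_noise_sd = 12, saturation = 65535,
                         hot_pixel_frac = 0, qe_sigma = 0.003,
                         qe_points = cbind(c(840, 940), c(0.60, 0.40))) {
  stopifnot(rows >= 1, cols >= 2, dark_noise_sd >= 0,
            qe_sigma >= 0, qe_sigma <= 0.01,
            hot_pixel_frac >= 0, hot_pixel_frac < 1)
  structure(list(rows = rows, cols = cols, pitch_um = pitch_um,
                 dark_noise_sd = dark_noise_sd, saturation = saturation,
                 hot_pixel_frac = hot_pixel_frac, qe_sigma = qe_sigma,
                 qe_points = qe_points),
            class = "sensor_model")
}

# spectral QE at wavelength(s), linear through the anchor points and
# extrapolated linearly, floored at a small positive value
sensor_qe <- function(sensor, wavelength_nm) {
  p <- sensor$qe_points
  slope <- (p[2, 2] - p[1, 2]) / (p[2, 1] - p[1, 1])
  pmax(p[1, 2] + slope * (wavelength_nm - p[1, 1]), 0.01)
}

#' Static per-pixel QE gain map
#'
#' Pixel-to-pixel QE variation is static in time (it cannot be averaged out
#' over repeated frames), so the map is drawn once per instrument instance
#' and reused for every frame: i.i.d. multiplicative gains ~ N(1, sigma).
#'
#' @param sensor a [sensor_model()].
#' @param qe_sigma relative std of the gains (default: the sensor's).
#' @param seed integer seed.
#' @return a `rows x cols` numeric matrix of gains.
#' @export
make_qe_map <- function(sensor, qe_sigma = sensor$qe_sigma, seed = 1) {
  stopifnot(qe_sigma >= 0, qe_sigma <= 0.01)
  with_seed(seed, {
    matrix(stats::rnorm(sensor$rows * sensor$cols, 1, qe_sigma),
           nrow = sensor$rows)
  })
}

#' Optics model
#'
#' Spectrograph optics: a quadratic pixel-to-wavelength map spanning roughly
#' 800-960 nm across the columns, the apparatus (line-spread) width on the
#' sensor from the imaged slit and the pixel aperture, end-to-end optical
#' throughput, and the disjoint row windows where the reference band, the
#' main band, and the spatially offset out-of-focus fluorescence band land.
#'
#' @param wavelength_coefs coefficients `(a0, a1, a2)` of
#'   `lambda(c) = a0 + a1*c + a2*c^2` in nm, with `c` the 0-based column.
#' @param slit_image_um imaged slit width on the sensor (25 um slit zooms to
#'   5.4 um).
#' @param pixel_um pixel aperture width in um.
#' @param throughput end-to-end optical throughput (~0.92).
#' @param ref_rows,main_rows,offset_rows disjoint row index windows.
#' @return a list of class `optics_model`.
#' @export
optics_model <- function(wavelength_coefs = c(800, 0.08, 1e-7),
                         slit_image_um = 5.4, pixel_um = 4,
                         throughput = 0.92,
                         ref_rows = 8:12, main_rows = 40:44,
                         offset_rows = 50:60) {
  if (length(intersect(ref_rows, main_rows)) ||
      length(intersect(ref_rows, offset_rows)) ||
      length(intersect(main_rows, offset_rows))) {
    abort("band row windows must be disjoint")
  }
  stopifnot(throughput > 0, throughput <= 1, slit_image_um > 0, pixel_um > 0)
  structure(list(wavelength_coefs = wavelength_coefs,
                 slit_image_um = slit_image_um, pixel_um = pixel_um,
                 throughput = throughput, ref_rows = ref_rows,
                 main_rows = main_rows, offset_rows = offset_rows),
            class = "optics_model")
}

#' Pixel-to-wavelength map and its inverse
#'
#' @param optics an [optics_model()].
#' @param col 1-based column index (may be fractional).
#' @param wavelength_nm wavelength in nm.
#' @param cols total number of columns (for the inverse's validity range).
#' @return `wavelength_of_col` gives nm; `col_of_wavelength` gives the
#'   fractional 1-based column (NA outside the mapped band).
#' @export
wavelength_of_col <- function(optics, col) {
  a <- optics$wavelength_coefs
  c0 <- col - 1
  a[1] + a[2] * c0 + a[3] * c0^2
}

#' @rdname wavelength_of_col
#' @export
col_of_wavelength <- function(optics, wavelength_nm, cols = 2000) {
  a <- optics$wavelength_coefs
  # invert the (strictly increasing) quadratic analytically
  if (a[3] == 0) {
    c0 <- (wavelength_nm - a[1]) / a[2]
  } else {
    disc <- a[2]^2 - 4 * a[3] * (a[1] - wavelength_nm)
    c0 <- ifelse(disc >= 0, (-a[2] + sqrt(pmax(disc, 0))) / (2 * a[3]), NA_real_)
  }
  out <- c0 + 1
  out[out < 1 | out > cols] <- NA_real_
  out
}

# local dispersion in nm per pixel at (fractional) column
dispersion_of_col <- function(optics, col) {
  a <- optics$wavelength_coefs
  a[2] + 2 * a[3] * (col - 1)
}

#' Instrument configuration
#'
#' Bundles the lasers (785 nm fingerprint + 675 nm high-frequency), sensor,
#' optics, the built-in polystyrene reference line list and the reference
#' band amplitude. At construction it checks self-consistency: at least
#' three reference lines must land inside the sensor band for each laser.
#'
#' @param lasers named list of [laser_model()]s.
#' @param sensor a [sensor_model()].
#' @param optics an [optics_model()].
#' @param ref_lines reference [line_list()] (default: built-in polystyrene).
#' @param ref_amplitude reference band area scale, counts per second per
#'   unit relative line intensity at nominal power. The default puts the
#'   signal-to-noise ratio of a 1 s reference spectrum (per the 1001 cm^-1
#'   amplitude / 1700-2100 cm^-1 RMS procedure) near the ~1250 the
#'   instrument achieves.
#' @return a list of class `instrument_config`.
#' @export
instrument_config <- function(lasers = list(`785` = laser_model(785),
                                            `675` = laser_model(675)),
                              sensor = sensor_model(),
                              optics = optics_model(),
                              ref_lines = builtin_linelist("polystyrene"),
                              ref_amplitude = 1.8e5) {
  for (nm in names(lasers)) {
    lam <- vapply(ref_lines$center_cm1, function(s) {
      nu <- 1e7 / lasers[[nm]]$nominal_nm - s
      if (nu <= 0) return(NA_real_)
      1e7 / nu
    }, numeric(1))
    inside <- sum(!is.na(col_of_wavelength(optics, lam, sensor$cols)), na.rm = TRUE)
    if (inside < 3) {
      abort(sprintf(
        "laser %s nm: only %d reference lines inside the sensor band", nm, inside))
    }
  }
  cfg <- structure(list(lasers = lasers, sensor = sensor, optics = optics,
                        ref_lines = ref_lines, ref_amplitude = ref_amplitude),
                   class = "instrument_config")
  attr(cfg, "hash") <- config_hash(paste(utils::capture.output(utils::str(
    cfg, digits.d = 10, vec.len = 1e4)), collapse = "\n"))
  cfg
}

# expected (noise-free) column profile of one spectral band, summed over the
# band's rows. `lines` in cm-1; fluor is NULL or function(lambda_nm) ->
# counts/s per column at unit power/throughput/QE=1.
band_expectation <- function(config, state, lines, amplitude,
                             laser_linewidth_nm, exposure_s,
                             fluor = NULL) {
  sensor <- config$sensor
  optics <- config$optics
  cols <- sensor$cols
  out <- numeric(cols)
  grid <- seq_len(cols)
  app_fwhm_px <- sqrt(optics$slit_image_um^2 + optics$pixel_um^2) /
    sensor$pitch_um
  any_visible <- is.null(lines)
  for (ci in seq_len(nrow(state$components))) {
    lam_c <- state$components$wavelength_nm[ci]
    w <- state$components$weight[ci]
    if (!is.null(lines)) {
      for (li in seq_len(nrow(lines))) {
        row <- lines[li, ]
        nu <- 1e7 / lam_c - row$center_cm1
        if (nu <= 0) next
        lam <- 1e7 / nu
        col <- col_of_wavelength(optics, lam, cols)
        if (is.na(col)) next
        any_visible <- TRUE
        disp <- dispersion_of_col(optics, col) # nm / px
        nm_per_cm1 <- lam^2 / 1e7
        # widths in pixels: natural line, laser linewidth, apparatus
        lw_px <- laser_linewidth_nm / disp
        if (row$shape == "voigt") {
          g_nat <- row$gauss_fwhm * nm_per_cm1 / disp
          l_px <- row$lorentz_fwhm * nm_per_cm1 / disp
        } else if (row$shape == "gaussian") {
          g_nat <- row$fwhm_cm1 * nm_per_cm1 / disp
          l_px <- 0
        } else {
          g_nat <- 0
          l_px <- row$fwhm_cm1 * nm_per_cm1 / disp
        }
        g_px <- sqrt(g_nat^2 + lw_px^2 + app_fwhm_px^2)
        area <- row$rel_intensity * amplitude * w * state$power *
          exposure_s * optics$throughput * sensor_qe(sensor, lam)
        prof <- if (l_px > 0 && g_px > 0) {
          pseudo_voigt_profile(grid, col, g_px, l_px)
        } else if (l_px > 0) {
          lorentz_profile(grid, col, l_px)
        } else {
          gauss_profile(grid, col, g_px)
        }
        out <- out + area * prof
      }
    }
    if (!is.null(fluor)) {
      lam_grid <- wavelength_of_col(optics, grid)
      out <- out + fluor(lam_grid) * w * state$power * exposure_s *
        optics$throughput * sensor_qe(sensor, lam_grid)
    }
  }
  if (!any_visible) abort("sample invisible: all lines outside the sensor band")
  out
}

#' Expected band profiles for a frame (simulation truth)
#'
#' Noise-free expected counts per column, summed over each band's rows, for
#' the reference, main and offset-fluorescence bands. This is the oracle the
#' renderer perturbs with noise; tests compare extracted channels against it.
#'
#' @param config an [instrument_config()].
#' @param state a [laser_state()].
#' @param sample sample description: a list with elements `lines` (a
#'   [line_list()] or NULL), `amplitude` (area counts/s per unit relative
#'   intensity), and optional `fluorescence`, `offset_fluorescence`
#'   (functions of wavelength in nm giving counts/s per column).
#' @param exposure_s exposure time in s.
#' @param laser which laser's linewidth applies (name in `config$lasers`);
#'   defaults to the one closest to the state's mean wavelength.
#' @return list with numeric vectors `reference`, `main`, `offset`.
#' @export
expected_bands <- function(config, state, sample, exposure_s = 1,
                           laser = NULL) {
  if (is.null(laser)) {
    center <- sum(state$components$wavelength_nm * state$components$weight)
    nominal <- vapply(config$lasers, `[[`, numeric(1), "nominal_nm")
    laser <- names(config$lasers)[which.min(abs(nominal - center))]
  }
  lw <- config$lasers[[laser]]$linewidth_nm
  ref <- band_expectation(config, state, config$ref_lines,
                          config$ref_amplitude, lw, exposure_s)
  main <- band_expectation(config, state, sample$lines,
                           sample$amplitude %||% 1, lw, exposure_s,
                           fluor = sample$fluorescence)
  offset <- if (!is.null(sample$offset_fluorescence)) {
    band_expectation(config, state, NULL, 0, lw, exposure_s,
                     fluor = sample$offset_fluorescence)
  } else {
    numeric(config$sensor$cols)
  }
  list(reference = ref, main = main, offset = offset)
}

#' Render one synthetic CMOS frame
#'
#' Deposits the expected reference, main and offset-fluorescence band
#' profiles into their row windows, applies the static per-pixel QE gain
#' map, then (optionally) adds Poisson shot noise, Gaussian dark+read noise
#' and hot pixels, and clips to 16 bits. With `noise = FALSE` and a unit QE
#' map the frame is the exact expectation and rendering is deterministic.
#'
#' @inheritParams expected_bands
#' @param seed integer seed for the frame's noise.
#' @param qe_map per-pixel gain matrix from [make_qe_map()]; default all 1.
#' @param noise logical: add shot + dark noise and hot pixels?
#' @return a `sensor_frame`: list with integer matrix `counts` and a
#'   `sidecar` carrying the true [laser_state()], seed, exposure and config
#'   hash.
#' @export
render_frame <- function(config, state, sample, exposure_s = 1, seed = 1,
                         qe_map = NULL, noise = TRUE, laser = NULL) {
  stopifnot(exposure_s > 0)
  sensor <- config$sensor
  optics <- config$optics
  bands <- expected_bands(config, state, sample, exposure_s, laser)
  mean_mat <- matrix(0, sensor$rows, sensor$cols)
  for (b in list(list(rows = optics$ref_rows, v = bands$reference),
                 list(rows = optics$main_rows, v = bands$main),
                 list(rows = optics$offset_rows, v = bands$offset))) {
    rr <- b$rows + 1L # row windows are 0-based like columns in the optics map
    for (r in rr) mean_mat[r, ] <- mean_mat[r, ] + b$v / length(rr)
  }
  if (!is.null(qe_map)) mean_mat <- mean_mat * qe_map
  counts <- with_seed(seed, {
    m <- if (noise) {
      shot <- matrix(stats::rpois(length(mean_mat), lambda = mean_mat),
                     nrow = sensor$rows)
      dark <- matrix(stats::rnorm(length(mean_mat), 0,
                                  sensor$dark_noise_sd * sqrt(exposure_s)),
                     nrow = sensor$rows)
      shot + dark
    } else {
      mean_mat
    }
    if (noise && sensor$hot_pixel_frac > 0) {
      n_hot <- max(1L, round(sensor$hot_pixel_frac * length(m)))
      idx <- sample.int(length(m), n_hot)
      m[idx] <- stats::runif(n_hot, 2e4, sensor$saturation)
    }
    m
  })
  counts <- pmin(pmax(round(counts), 0), sensor$saturation)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 sidecar = list(laser_state = state, power = state$power,
                                exposure_s = exposure_s, seed = seed,
                                config_hash = attr(config, "hash"))),
            class = "sensor_frame")
}

#' @export
print.sensor_frame <- function(x, ...) {
  cat(sprintf("<sensor_frame %d x %d, max %d, exposure %gs>\n",
              nrow(x$counts), ncol(x$counts), max(x$counts),
              x$sidecar$exposure_s))
  invisible(x)
}

#' Write / read a frame as plain 16-bit PGM plus JSON sidecar
#'
#' Frames are stored as plain (P2, ASCII) PGM with a 65535 maxval, one file
#' per frame, with the simulation truth sidecar next to it
#' (`<stem>.json`).
#'
#' @param frame a `sensor_frame`.
#' @param path path of the `.pgm` file.
#' @return `write_frame` returns `path` invisibly; `read_frame` returns a
#'   `sensor_frame` (sidecar loaded if present).
#' @export
write_frame <- function(frame, path) {
  m <- frame$counts
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "65535"), con)
  apply(m, 1, function(r) writeLines(paste(r, collapse = " "), con))
  sc <- frame$sidecar
  if (!is.null(sc)) {
    st <- sc$laser_state
    jsonlite::write_json(
      list(laser_state = list(components = as.data.frame(st$components),
                              power = st$power),
           power = sc$power, exposure_s = sc$exposure_s, seed = sc$seed,
           config_hash = sc$config_hash),
      sub("\\.pgm$", ".json", path), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") abort("only plain (P2) PGM frames are supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.integer(toks[-(1:4)])
  counts <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  side_path <- sub("\\.pgm$", ".json", path)
  sidecar <- NULL
  if (file.exists(side_path)) {
    j <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    sidecar <- list(
      laser_state = laser_state(j$laser_state$components$wavelength_nm,
                                j$laser_state$components$weight,
                                power = j$laser_state$power),
      power = j$power, exposure_s = j$exposure_s, seed = j$seed,
      config_hash = j$config_hash)
  }
  structure(list(counts = counts, sidecar = sidecar), class = "sensor_frame")
}
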