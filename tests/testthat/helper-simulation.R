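# Shared fixtures: a linear-dispersion instrument keeps pixel shifts exact
# and makes oracle bookkeeping simple; the quadratic default map is
# exercised where the map itself matters.

linear_instrument <- function(ref_amplitude = 1.8e5, ...) {
  instrument_config(
    optics = optics_model(wavelength_coefs = c(800, 0.08, 0)),
    ref_amplitude = ref_amplitude, ...)
}

polystyrene_sample <- function(amplitude = 1.5e5) {
  list(lines = builtin_linelist("polystyrene"), amplitude = amplitude)
}

polypropylene_sample <- function(amplitude = 1.5e5) {
  list(lines = builtin_linelist("polypropylene"), amplitude = amplitude)
}

# trapezoid area of a spectrum over a window, above a linear edge baseline
window_area <- function(s, center, halfwidth = 20) {
  w <- s$axis >= center - halfwidth & s$axis <= center + halfwidth
  a <- s$axis[w]
  y <- s$intensity[w]
  base <- y[1] + (y[length(y)] - y[1]) * (a - a[1]) / (a[length(a)] - a[1])
  pracma::trapz(a, y - base)
}

# render a warm-up sequence of frames and run the default pipeline
simulate_and_calibrate <- function(n_frames, config = linear_instrument(),
                                   sample = polystyrene_sample(),
                                   drift_nm = 0.3, tau_s = 60,
                                   power_rel_sd = 0, frame_period_s = 2,
                                   seed = 1, noise = TRUE, qe_map = NULL,
                                   pipeline = pipeline_config(config)) {
  laser <- laser_model(785, drift_nm = drift_nm, drift_tau_s = tau_s,
                       power_rel_sd = power_rel_sd)
  states <- simulate_laser_sequence(laser, n_frames, frame_period_s, seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    render_frame(config, states$state[[i]], sample, exposure_s = 1,
                 seed = seed * 1000L + i, qe_map = qe_map, noise = noise)
  })
  list(states = states, frames = frames,
       result = run_pipeline(pipeline, frames))
}
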