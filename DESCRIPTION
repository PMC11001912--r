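Package: reframan
Title: Reference-Channel Raman Spectrometer Processing and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for dual-channel Raman spectrometers that carry a
    built-in polystyrene reference channel on the same sensor as the main
    channel. Provides per-acquisition wavenumber and intensity calibration from
    the reference channel, laser mode-hop kernel estimation and deconvolution,
    apparatus-function deblurring with Richardson-Lucy iteration, shifted
    excitation Raman difference spectroscopy (SERDS) separation of Raman and
    fluorescence, quantum-efficiency drift averaging, blackbody response
    correction, and a partial-least-squares quantification layer with detection
    limits. Includes a physics-based simulator of the instrument's CMOS frames
    (laser thermal drift and mode hops, power fluctuation, apparatus blur,
    pixel-to-pixel quantum-efficiency variation, dark and shot noise, hot
    pixels, fluorescence backgrounds) so every processing stage can be
    exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    Matrix,
    signal,
    pracma,
    minpack.lm,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
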