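#' Construct a spectrum
#'
#' A `raman_spectrum` is a tibble with columns `axis` and `intensity` plus
#' metadata attributes: the axis kind (detector pixel, absolute wavelength in
#' nm, or Raman shift in cm^-1), the channel it came from (`main` or
#' `reference`), the exposure time and an acquisition id. All processing
#' functions in the package accept and return this class, so results chain
#' with the pipe.
#'
#' @param axis numeric vector, strictly increasing, length >= 2. Pixel axes
#'   must be integer-valued.
#' @param intensity numeric vector of the same length; all values finite.
#' @param kind one of `"pixel"`, `"wavelength_nm"`, `"raman_shift_cm1"`.
#' @param channel `"main"` or `"reference"`.
#' @param exposure_s exposure time in seconds.
#' @param acquisition free-form acquisition id.
#' @return a tibble of class `raman_spectrum`.
#' @export
#' @examples
#' s <- raman_spectrum(seq(400, 1800, by = 0.5),
#'                     dnorm(seq(400, 1800, by = 0.5), 1001, 3))
#' s
raman_spectrum <- function(axis, intensity,
                           kind = c("raman_shift_cm1", "wavelength_nm", "pixel"),
                           channel = "main", exposure_s = 1, acquisition = NA_character_) {
  kind <- match.arg(kind)
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) < 2L) rlang::abort("axis must have length >= 2")
  if (length(axis) != length(intensity)) {
    rlang::abort("axis and intensity lengths differ")
  }
  if (any(!is.finite(axis)) || any(diff(axis) <= 0)) {
    rlang::abort("axis must be finite and strictly increasing")
  }
  if (kind == "pixel" && any(axis != round(axis))) {
    rlang::abort("pixel axes must be integer-valued")
  }
  if (any(!is.finite(intensity))) rlang::abort("intensities must be finite")
  out <- tibble::tibble(axis = axis, intensity = intensity)
  class(out) <- c("raman_spectrum", class(out))
  attr(out, "axis_kind") <- kind
  attr(out, "channel") <- channel
  attr(out, "exposure_s") <- exposure_s
  attr(out, "acquisition") <- acquisition
  out
}

#' Axis kind of a spectrum
#' @param x a `raman_spectrum`.
#' @return one of `"pixel"`, `"wavelength_nm"`, `"raman_shift_cm1"`.
#' @export
axis_kind <- function(x) attr(x, "axis_kind")

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum: %d points, axis %s [%.6g, %.6g], channel %s>\n",
              nrow(x), axis_kind(x), min(x$axis), max(x$axis),
              attr(x, "channel") %||% "?"))
  NextMethod()
}

# carry spectrum attributes onto a modified copy
spectrum_like <- function(template, axis = template$axis,
                          intensity = template$intensity, kind = axis_kind(template)) {
  raman_spectrum(axis, intensity, kind,
                 channel = attr(template, "channel") %||% "main",
                 exposure_s = attr(template, "exposure_s") %||% 1,
                 acquisition = attr(template, "acquisition") %||% NA_character_)
}

#' Plot a spectrum
#' @param object a `raman_spectrum`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot raman_spectrum
#' @export
autoplot.raman_spectrum <- function(object, ...) {
  lab <- switch(axis_kind(object),
                pixel = "Pixel",
                wavelength_nm = "Wavelength (nm)",
                raman_shift_cm1 = expression(paste("Raman shift (", cm^-1, ")")))
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$axis, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = lab, y = "Intensity (a.u.)")
}

#' Read / write a spectrum as two-column delimited text
#'
#' The on-disk format is two whitespace-separated columns (axis value,
#' intensity) with `#`-prefixed header lines carrying the axis kind and
#' metadata.
#'
#' @param x a `raman_spectrum`.
#' @param path file path.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum` returns
#'   a `raman_spectrum`.
#' @export
write_spectrum <- function(x, path) {
  hdr <- c(sprintf("# axis_kind: %s", axis_kind(x)),
           sprintf("# channel: %s", attr(x, "channel") %||% "main"),
           sprintf("# exposure_s: %s", format(attr(x, "exposure_s") %||% 1)),
           sprintf("# acquisition: %s", attr(x, "acquisition") %||% NA))
  body <- sprintf("%.10g %.10g", x$axis, x$intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key, default) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  raman_spectrum(dat[[1]], dat[[2]],
                 kind = get_field("axis_kind", "raman_shift_cm1"),
                 channel = get_field("channel", "main"),
                 exposure_s = as.numeric(get_field("exposure_s", "1")),
                 acquisition = get_field("acquisition", NA_character_))
}

#' Default working grid for calibrated spectra
#'
#' Uniform 0.5 cm^-1 grid spanning the instrument's combined 400-4000 cm^-1
#' range (>= 10 grid points per 7 cm^-1 resolution element).
#'
#' @param from,to,by grid limits and step in cm^-1.
#' @return numeric vector of Raman shifts.
#' @export
standard_shift_grid <- function(from = 400, to = 4000, by = 0.5) {
  seq(from, to, by = by)
}
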