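#' Mode-hop broadening kernel
#'
#' A mode hop within one exposure multiplies the spectrum by a few-spike
#' kernel in pixel space: each emission component deposits a shifted copy of
#' the spectrum. The kernel holds integer pixel offsets and non-negative
#' weights normalized to unit sum (finite support, at most 15 taps).
#'
#' @param offsets integer pixel offsets.
#' @param weights non-negative weights (normalized internally).
#' @return a list of class `broadening_kernel`.
#' @export
broadening_kernel <- function(offsets, weights) {
  stopifnot(length(offsets) == length(weights), length(offsets) >= 1,
            all(offsets == round(offsets)), all(weights >= 0),
            sum(weights) > 0)
  if (length(offsets) > 15) abort("kernel support exceeds 15 pixels")
  o <- order(offsets)
  structure(list(offsets = as.integer(offsets[o]),
                 weights = weights[o] / sum(weights)),
            class = "broadening_kernel")
}

# apply a sparse offset kernel: out[i] = sum_j w_j x[i - o_j]
apply_kernel <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (j in seq_along(kernel$offsets)) {
    o <- kernel$offsets[j]
    src <- seq_len(n) - o
    ok <- src >= 1L & src <= n
    out[ok] <- out[ok] + kernel$weights[j] * x[src[ok]]
  }
  out
}

# mirror kernel (adjoint), used in the Richardson-Lucy back-projection
flip_kernel <- function(kernel) {
  o <- order(-kernel$offsets)
  structure(list(offsets = as.integer(-kernel$offsets[o]),
                 weights = kernel$weights[o]),
            class = "broadening_kernel")
}

#' Estimate the mode-hop kernel from the reference channel
#'
#' Solves `observed ~ clean (*) k` for the few-spike kernel `k` by
#' non-negative least squares over integer offsets, with first-difference
#' Tikhonov smoothing whose weight is set by the discrepancy principle
#' (residual comparable to the noise level). The clean reference is the
#' synthesized or previously measured hop-free reference spectrum on the
#' same pixel grid.
#'
#' @param observed,clean `raman_spectrum`s on the same pixel grid.
#' @param max_offset kernel half-support in pixels (default 7).
#' @param noise_sd per-point noise std of `observed`; estimated from the
#'   high-frequency content when NULL.
#' @param max_resid_frac error if the residual energy exceeds this fraction
#'   of the observed energy (default 0.10).
#' @param lambda first-difference Tikhonov weight on the kernel taps. The
#'   default 0 keeps the estimator unbiased: shifted copies of the
#'   reference are nearly collinear, so any smoothing spreads a genuine
#'   spike kernel at almost no residual cost. `"auto"` selects the largest
#'   weight whose residual stays at the attained noise floor (discrepancy
#'   principle), useful for dense kernels.
#' @param support_frac only columns where the clean reference exceeds this
#'   fraction of its maximum (padded by `max_offset`) enter the fit.
#' @return a `broadening_kernel` with attributes `residual_frac` and
#'   `lambda`.
#' @export
estimate_hop_kernel <- function(observed, clean, max_offset = 7,
                                noise_sd = NULL, max_resid_frac = 0.10,
                                lambda = 0, support_frac = 0.05) {
  y <- observed$intensity
  x <- clean$intensity
  if (length(y) != length(x)) abort("spectra must share a pixel grid")
  offsets <- -max_offset:max_offset
  n <- length(y)
  A <- vapply(offsets, function(o) {
    out <- numeric(n)
    src <- seq_len(n) - o
    ok <- src >= 1L & src <= n
    out[ok] <- x[src[ok]]
    out
  }, numeric(n))
  if (is.null(noise_sd)) {
    noise_sd <- stats::mad(diff(y)) / sqrt(2)
  }
  # fit only where the blurred clean spectrum carries signal: noise-only
  # columns would otherwise dominate both the fit and the residual check
  sup <- which(x > support_frac * max(x))
  sup <- unique(pmin(pmax(
    rep(sup, each = 2 * max_offset + 1) + offsets, 1), n))
  A <- A[sup, , drop = FALSE]
  y <- y[sup]
  m <- length(offsets)
  D <- diff(diag(m)) # first differences over the kernel taps
  target <- sqrt(length(y)) * max(noise_sd, 1e-12)
  solve_lambda <- function(lam) {
    Aa <- rbind(A, lam * D)
    ya <- c(y, numeric(nrow(D)))
    k <- pracma::lsqnonneg(Aa, ya)$x
    list(k = k, resid = sqrt(sum((A %*% k - y)^2)))
  }
  best <- solve_lambda(0)
  best_lam <- 0
  if (identical(lambda, "auto")) {
    # discrepancy principle: strongest smoothing whose residual stays at
    # the attained noise floor
    allowed <- 1.02 * max(best$resid, min(target, 2 * best$resid))
    for (lam in max(abs(A)) * 10^seq(-4, 0, length.out = 9)) {
      s <- solve_lambda(lam)
      if (s$resid <= allowed) {
        best_lam <- lam
        best <- s
      }
    }
  } else if (lambda > 0) {
    best <- solve_lambda(lambda)
    best_lam <- lambda
  }
  k <- best$k
  resid_frac <- sqrt(sum((A %*% k - y)^2) / sum(y^2))
  if (sum(k) <= 0 || resid_frac > max_resid_frac) {
    abort("kernel unreliable: residual exceeds 10% of observed energy")
  }
  out <- broadening_kernel(offsets, k)
  keep <- out$weights > 1e-6
  out <- broadening_kernel(out$offsets[keep], out$weights[keep])
  attr(out, "residual_frac") <- resid_frac
  attr(out, "lambda") <- best_lam
  out
}

# Richardson-Lucy iteration for a sparse offset kernel or a dense
# apparatus profile. Preserves non-negativity; flux is conserved up to edge
# leakage (spectra are expected to decay to baseline at the edges).
richardson_lucy <- function(y, kernel, iterations = 30, tol = 1e-5) {
  y <- pmax(y, 0)
  x <- y
  kf <- flip_kernel(kernel)
  eps <- 1e-12
  for (it in seq_len(iterations)) {
    blur <- apply_kernel(x, kernel)
    ratio <- y / pmax(blur, eps)
    x_new <- x * apply_kernel(ratio, kf)
    delta <- sum(abs(x_new - x)) / max(sum(abs(x)), eps)
    x <- x_new
    if (delta < tol) break
  }
  x
}

#' Deconvolve the mode-hop kernel from the main channel
#'
#' Richardson-Lucy iteration with the estimated few-spike kernel:
#' non-negativity is preserved and total intensity is conserved (within
#' 0.1% for spectra that decay to baseline at the grid edges).
#'
#' @param x a `raman_spectrum` (pixel grid).
#' @param kernel a `broadening_kernel`.
#' @param iterations maximum iterations (default 30).
#' @param tol early-stopping threshold on the relative change per iteration.
#' @return the deconvolved `raman_spectrum`.
#' @export
deconvolve_with_kernel <- function(x, kernel, iterations = 30, tol = 1e-5) {
  if (length(kernel$offsets) == 1 && kernel$offsets == 0L) {
    return(x)
  }
  spectrum_like(x, intensity = richardson_lucy(x$intensity, kernel,
                                               iterations, tol))
}

#' Apparatus function of the spectrometer
#'
#' @param offset_cm1 uniform offset grid (cm^-1), centered on 0.
#' @param value non-negative profile values (normalized to unit area).
#' @return a tibble of class `apparatus_function` with attribute
#'   `fwhm_cm1`.
#' @export
apparatus_function <- function(offset_cm1, value) {
  stopifnot(length(offset_cm1) == length(value), all(value >= -1e-12))
  value <- pmax(value, 0)
  area <- pracma::trapz(offset_cm1, value)
  if (area <= 0) abort("apparatus profile has zero area")
  out <- tibble::tibble(offset_cm1 = offset_cm1, value = value / area)
  class(out) <- c("apparatus_function", class(out))
  attr(out, "fwhm_cm1") <- profile_fwhm(offset_cm1, out$value)
  out
}

# FWHM of a sampled profile by linear interpolation at half maximum
profile_fwhm <- function(x, y) {
  i <- which.max(y)
  half <- y[i] / 2
  left <- which(y[seq_len(i)] <= half)
  right <- which(y[i:length(y)] <= half)
  xl <- if (length(left)) {
    j <- max(left)
    stats::approx(y[c(j, j + 1)], x[c(j, j + 1)], xout = half)$y
  } else {
    x[1]
  }
  xr <- if (length(right)) {
    j <- i + min(right) - 1
    stats::approx(y[c(j - 1, j)], x[c(j - 1, j)], xout = half)$y
  } else {
    x[length(x)]
  }
  xr - xl
}

#' Measure the apparatus function from a diamond spectrum
#'
#' The first-order diamond line has a natural Lorentzian width of about
#' 1.8 cm^-1; deconvolving that known profile out of the measured line
#' (regularized division in the Fourier domain, clipped to non-negative and
#' renormalized) leaves the spectrometer's line-spread (apparatus) function.
#'
#' @param x measured diamond `raman_spectrum` on a uniform Raman-shift grid.
#' @param natural_fwhm natural Lorentzian FWHM of the line (cm^-1).
#' @param window half-width (cm^-1) of the analysis window around the line.
#' @param reg relative Tikhonov regularization of the spectral division.
#' @param noise_reg Wiener-style weight on the estimated per-point noise
#'   power; suppresses the high frequencies where the Lorentzian transform
#'   has decayed below the noise floor.
#' @return an [apparatus_function()] (attribute `fwhm_cm1` reports its
#'   width).
#' @export
estimate_apparatus_function <- function(x, natural_fwhm = 1.8, window = 30,
                                        reg = 1e-4, noise_reg = 100) {
  dx <- diff(x$axis)
  if (diff(range(dx)) > 1e-6 * mean(dx)) abort("uniform grid required")
  dx <- mean(dx)
  i <- which.max(x$intensity)
  base <- stats::median(x$intensity)
  if (x$intensity[i] <= base + 6 * stats::mad(x$intensity)) {
    abort("no dominant line found")
  }
  half_n <- round(window / dx)
  lo <- max(1, i - half_n)
  hi <- min(nrow(x), i + half_n)
  seg <- x$intensity[lo:hi]
  seg <- pmax(seg - min(seg), 0)
  n <- length(seg)
  center <- i - lo + 1
  off <- (seq_len(n) - center) * dx
  nat <- lorentz_profile(off, 0, natural_fwhm) * dx
  # zero-phase alignment: rotate both so their centers sit at index 1
  rot <- function(v) c(v[center:n], v[seq_len(center - 1)])
  Fm <- stats::fft(rot(seg / sum(seg)))
  Fn <- stats::fft(rot(nat))
  sigma_rel <- stats::mad(diff(x$intensity)) / sqrt(2) / sum(seg)
  denom <- Mod(Fn)^2 + reg * max(Mod(Fn)^2) +
    noise_reg * n * sigma_rel^2
  a <- Re(stats::fft(Fm * Conj(Fn) / denom, inverse = TRUE)) / n
  a <- c(a[(n - center + 2):n], a[seq_len(n - center + 1)]) # undo rotation
  apparatus_function(off, pmax(a, 0) / dx)
}

#' Deblur a spectrum with the measured apparatus function
#'
#' Richardson-Lucy deconvolution of the apparatus (line-spread) function,
#' with early stopping when the relative change per iteration falls below
#' `tol`. Non-negative and flux-conserving within 0.1% on spectra that
#' decay to baseline at the edges.
#'
#' @param x a `raman_spectrum` on a uniform grid.
#' @param apparatus an [apparatus_function()].
#' @param iterations maximum Richardson-Lucy iterations.
#' @param tol early-stopping threshold.
#' @return the deblurred `raman_spectrum`.
#' @export
deblur <- function(x, apparatus, iterations = 30, tol = 1e-5) {
  dx <- diff(x$axis)
  if (diff(range(dx)) > 1e-6 * mean(dx)) abort("uniform grid required")
  dx <- mean(dx)
  # sample the apparatus profile on the spectrum's grid step
  span <- max(abs(apparatus$offset_cm1))
  off <- seq(-span, span, by = dx)
  w <- stats::approx(apparatus$offset_cm1, apparatus$value, xout = off,
                     rule = 2)$y
  w <- pmax(w, 0)
  kernel <- broadening_kernel_dense(round(off / dx), w)
  spectrum_like(x, intensity = richardson_lucy(x$intensity, kernel,
                                               iterations, tol))
}

# dense kernels may exceed the 15-tap limit of broadening_kernel(); same
# structure without the sparse-support restriction
broadening_kernel_dense <- function(offsets, weights) {
  o <- order(offsets)
  structure(list(offsets = as.integer(offsets[o]),
                 weights = weights[o] / sum(weights)),
            class = "broadening_kernel")
}

#' Fit a line profile and report its FWHM
#'
#' Least-squares fit of a single Gaussian, Lorentzian or pseudo-Voigt
#' profile (plus constant baseline) around an approximate center.
#'
#' @param x a `raman_spectrum`.
#' @param center_approx approximate line position (axis units).
#' @param shape `"voigt"` (pseudo-Voigt with free Gaussian and Lorentzian
#'   widths), `"gaussian"` or `"lorentzian"`.
#' @param window fit half-width in axis units.
#' @return a one-row tibble: `center`, `fwhm`, `gauss_fwhm`, `lorentz_fwhm`
#'   (NA unless Voigt), `amplitude`, `rmse`.
#' @export
fit_line_fwhm <- function(x, center_approx, shape = c("voigt", "gaussian",
                                                      "lorentzian"),
                          window = 25) {
  shape <- match.arg(shape)
  w <- x$axis >= center_approx - window & x$axis <= center_approx + window
  if (sum(w) < 8) abort("fit window too small")
  xa <- x$axis[w]
  ya <- x$intensity[w]
  b0 <- stats::quantile(ya, 0.1, names = FALSE)
  a0 <- max(ya) - b0
  c0 <- xa[which.max(ya)]
  f0 <- max(2 * mean(diff(xa)), sum(ya - b0 > a0 / 2) * mean(diff(xa)))
  fit <- switch(shape,
    gaussian = minpack.lm::nlsLM(
      ya ~ b + a * gauss_profile(xa, c, f),
      start = list(b = b0, a = a0 * f0, c = c0, f = f0),
      lower = c(-Inf, 0, min(xa), 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    lorentzian = minpack.lm::nlsLM(
      ya ~ b + a * lorentz_profile(xa, c, f),
      start = list(b = b0, a = a0 * f0, c = c0, f = f0),
      lower = c(-Inf, 0, min(xa), 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    voigt = minpack.lm::nlsLM(
      ya ~ b + a * pseudo_voigt_profile(xa, c, fg, fl),
      start = list(b = b0, a = a0 * f0, c = c0, fg = f0 * 0.7, fl = f0 * 0.4),
      lower = c(-Inf, 0, min(xa), 1e-3, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 300)))
  cf <- stats::coef(fit)
  fwhm <- switch(shape,
                 voigt = voigt_fwhm(cf[["fg"]], cf[["fl"]]),
                 cf[["f"]])
  tibble::tibble(center = cf[["c"]], fwhm = fwhm,
                 gauss_fwhm = if (shape == "voigt") cf[["fg"]] else NA_real_,
                 lorentz_fwhm = if (shape == "voigt") cf[["fl"]] else NA_real_,
                 amplitude = cf[["a"]], rmse = rms(stats::residuals(fit)))
}

#' Spectral resolution by quadrature deconvolution
#'
#' Removes a known intrinsic linewidth from a measured FWHM in quadrature:
#' `resolution = sqrt(measured^2 - intrinsic^2)` (the ASTM-style estimate
#' used with a calcite or diamond reference line).
#'
#' @param measured_fwhm fitted FWHM of the measured line.
#' @param intrinsic_fwhm natural linewidth of the reference line.
#' @return the resolution estimate, same units.
#' @export
resolution_from_fwhm <- function(measured_fwhm, intrinsic_fwhm) {
  if (any(measured_fwhm < intrinsic_fwhm)) {
    abort("measured FWHM must be >= the intrinsic FWHM")
  }
  sqrt(measured_fwhm^2 - intrinsic_fwhm^2)
}
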