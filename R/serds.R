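#' Per-acquisition excitation offsets from calibrations
#'
#' The non-stabilized laser drifts while warming up; the reference-channel
#' calibration measures the excitation wavenumber of every acquisition, so
#' the SERDS offsets come for free:
#' `delta_i = nu_laser,i - nu_laser,1` (cm^-1).
#'
#' @param calibrations list of `calibration_result`s (>= 2).
#' @param min_span error below this offset span in cm^-1 (default one grid
#'   step, 0.5).
#' @return numeric vector of offsets, first element 0.
#' @export
estimate_excitation_shifts <- function(calibrations, min_span = 0.5) {
  if (length(calibrations) < 2) abort("need at least 2 acquisitions")
  nus <- vapply(calibrations, `[[`, numeric(1), "laser_nu_cm1")
  offsets <- nus - nus[1]
  if (max(abs(offsets)) < min_span) {
    abort("insufficient excitation shift: laser drift spans < 1 grid step")
  }
  offsets
}

rolling_min <- function(y, width) {
  n <- length(y)
  half <- width %/% 2
  vapply(seq_len(n), function(i) {
    min(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# sparse linear-interpolation shift operator: (T f)(s) = f(s - delta) on a
# uniform grid; indices beyond the grid clamp to the nearest edge (the
# fluorescence extends smoothly past the recorded band, so constants are
# mapped to constants and no artificial edge step appears)
shift_matrix <- function(n, delta, step) {
  shift <- delta / step
  lo <- floor(shift)
  frac <- shift - lo
  i <- seq_len(n)
  j1 <- pmin(pmax(i - lo, 1L), n)      # f index for the integer part
  j2 <- pmin(pmax(i - lo - 1L, 1L), n)
  Matrix::sparseMatrix(
    i = c(i, i),
    j = c(j1, j2),
    x = c(rep(1 - frac, n), rep(frac, n)),
    dims = c(n, n))
}

#' Separate Raman and fluorescence from drift-shifted spectra
#'
#' On the calibrated Raman-shift axis the Raman features are pinned by the
#' reference-channel calibration, while fluorescence — fixed in absolute
#' wavelength — moves along with the excitation offset `delta_i`. The
#' separation solves
#' `min_{R >= 0, F} sum_i || S_i - R - F(s - delta_i) ||^2 + lambda ||D2 F||^2`
#' by alternating a non-negative update of the static Raman spectrum `R`
#' and a smoothness-penalized linear solve for the moving fluorescence
#' profile `F`, until the relative objective change falls below `tol`.
#'
#' A classical two-spectrum difference mode (`mode = "difference"`) is also
#' provided for comparison: it reports the first-vs-last difference
#' spectrum and a reconstruction from it, using only two acquisitions.
#'
#' @param spectra list of calibrated `raman_spectrum`s on a common uniform
#'   grid (>= 2).
#' @param offsets excitation offsets in cm^-1 from
#'   [estimate_excitation_shifts()].
#' @param lambda second-difference smoothness weight on the fluorescence
#'   profile. The default (`NULL`) scales with the grid so that the
#'   fluorescence retains roughly 10 effective degrees of freedom across
#'   the band.
#' @param max_iter,tol alternation limits.
#' @param mode `"joint"` (default) or `"difference"`.
#' @return a list of class `serds_result`: `raman` (non-negative
#'   `raman_spectrum`), `fluorescence` (profile on the first acquisition's
#'   shift axis; fixed in absolute wavelength), `fluorescence_penalized`
#'   (the raw output of the smoothness-penalized solve, before the
#'   zero-baseline convention moves the smooth envelope of R into F),
#'   `offsets`, `residual_norm`, `iterations`, `converged`.
#' @export
separate_raman_fluorescence <- function(spectra, offsets, lambda = NULL,
                                        max_iter = 50, tol = 1e-6,
                                        mode = c("joint", "difference")) {
  mode <- match.arg(mode)
  if (length(spectra) < 2) abort("need at least 2 spectra")
  if (length(offsets) != length(spectra)) {
    abort("one offset per spectrum required")
  }
  if (max(abs(offsets - offsets[1])) < 1e-12) {
    abort("insufficient excitation shift: all offsets identical")
  }
  ax <- spectra[[1]]$axis
  step <- mean(diff(ax))
  if (diff(range(diff(ax))) > 1e-6 * step) abort("uniform common grid required")
  S <- vapply(spectra, function(s) {
    if (length(s$axis) != length(ax) || any(abs(s$axis - ax) > 1e-9)) {
      abort("spectra must share a common grid")
    }
    s$intensity
  }, numeric(length(ax)))
  n <- length(ax)
  m <- ncol(S)

  if (mode == "difference") {
    d <- S[, m] - S[, 1]
    # reconstruct the static component by removing the shifted-difference:
    # R ~ mean(S) - smooth residual; report the difference spectrum itself
    R <- pmax(rowMeans(S) - stats::fitted(stats::smooth.spline(ax, rowMeans(S), df = 10)), 0)
    return(structure(list(
      raman = raman_spectrum(ax, R),
      fluorescence = raman_spectrum(ax, pmax(rowMeans(S) - R, 0)),
      difference = raman_spectrum(ax, d - min(d)),
      offsets = offsets, residual_norm = NA_real_, iterations = 0L,
      converged = TRUE), class = "serds_result"))
  }

  Tmats <- lapply(offsets, function(d) shift_matrix(n, d, step))
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  # Initialization resolves the smooth-split degeneracy (adding a smooth
  # term to R and removing it from F barely changes the objective): the
  # static Raman component cancels exactly in between-acquisition
  # differences, so F is first estimated from those alone.
  Tbar <- Reduce(`+`, Tmats) / m
  Amats <- lapply(Tmats, function(Ti) Ti - Tbar)
  Sc <- S - rowMeans(S)
  M_d <- Reduce(`+`, lapply(Amats, Matrix::crossprod))
  L <- Matrix::crossprod(D2)
  rhs_d <- Reduce(`+`, lapply(seq_len(m), function(i) {
    Matrix::crossprod(Amats[[i]], Sc[, i])
  }))
  # The difference operator is weak on smooth components, so its smoothing
  # weight must be set by the discrepancy principle (residual ~ noise),
  # not by the joint solve's effective df.
  sigma2 <- mean(apply(S, 2, function(v) {
    (stats::mad(diff(v)) / sqrt(2))^2
  }))
  rss_target <- 1.05 * n * m * max(sigma2, 1e-12) * (1 - 1 / m)
  solve_d <- function(lam) {
    Fd <- as.numeric(Matrix::solve(
      M_d + lam * L + Matrix::Diagonal(n, 1e-10 * max(1, mean(Matrix::diag(M_d)))),
      rhs_d))
    list(F = Fd,
         rss = sum(vapply(seq_len(m), function(i) {
           sum((as.numeric(Amats[[i]] %*% Fd) - Sc[, i])^2)
         }, numeric(1))))
  }
  scale_d <- mean(Matrix::diag(M_d))
  best_d <- solve_d(1e-6 * scale_d)
  for (lam in scale_d * 10^seq(-5, 6)) {
    s <- solve_d(lam)
    if (s$rss <= rss_target) best_d <- s else break
  }
  Fv <- best_d$F
  R <- pmax(rowMeans(S) - as.numeric(Tbar %*% Fv), 0)
  # joint smoothing weight, also by the discrepancy principle: the
  # strongest smoothing whose joint residual stays at the noise level
  M_j <- Reduce(`+`, lapply(Tmats, Matrix::crossprod))
  rhs_j <- function(Rv) {
    Reduce(`+`, lapply(seq_len(m), function(i) {
      Matrix::crossprod(Tmats[[i]], S[, i] - Rv)
    }))
  }
  if (is.null(lambda)) {
    rj <- rhs_j(R)
    rss_j <- function(lam) {
      Fj <- as.numeric(Matrix::solve(M_j + lam * L, rj))
      sum(vapply(seq_len(m), function(i) {
        sum((as.numeric(Tmats[[i]] %*% Fj) + R - S[, i])^2)
      }, numeric(1)))
    }
    target_j <- 1.05 * n * m * max(sigma2, 1e-12)
    lambda <- 1e-6 * m
    for (lam in m * 10^seq(-5, 8)) {
      if (rss_j(lam) <= target_j) lambda <- lam else break
    }
  }
  AtA <- M_j + lambda * L
  obj_old <- Inf
  it <- 0L
  converged <- FALSE
  rel_change <- Inf
  while (it < max_iter) {
    it <- it + 1L
    rhs <- Reduce(`+`, lapply(seq_len(m), function(i) {
      Matrix::crossprod(Tmats[[i]], S[, i] - R)
    }))
    Fv <- as.numeric(Matrix::solve(AtA, rhs))
    shifted <- vapply(seq_len(m), function(i) {
      as.numeric(Tmats[[i]] %*% Fv)
    }, numeric(n))
    R <- pmax(rowMeans(S - shifted), 0)
    resid <- S - shifted - R
    obj <- sum(resid^2) + lambda * sum(as.numeric(D2 %*% Fv)^2)
    rel_change <- abs(obj_old - obj) / max(obj_old, 1e-12)
    if (is.finite(obj_old) && rel_change <= tol) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  if (!converged && rel_change > 100 * tol) {
    warn("SERDS alternation did not converge; returning best iterate")
  }
  # move any flat baseline left in R into the fluorescence (the additive
  # constant between R and F is not identified by the shifts; convention:
  # the Raman spectrum touches zero)
  shifted <- vapply(Tmats, function(Ti) as.numeric(Ti %*% Fv), numeric(n))
  edge <- ceiling(max(abs(offsets)) / step) + 2L
  interior <- seq(edge + 1L, n - edge)
  U <- rowMeans(S - shifted)
  c0 <- max(0, stats::quantile(U[interior], 0.001, names = FALSE))
  Fv <- Fv + c0
  R <- pmax(U - c0, 0)
  # Smooth static structure is not separable from fluorescence by the
  # shifts alone; by convention it belongs to F, so the smooth lower
  # envelope of R is transferred over (a solid's separated Raman spectrum
  # returns to zero between lines).
  base <- rolling_min(R, width = max(21L, 2L * round(50 / step) + 1L))
  base <- pmax(stats::fitted(stats::smooth.spline(ax, base, df = 15)), 0)
  base <- pmin(base, R)
  Fv <- Fv + base
  R <- R - base
  structure(list(
    raman = raman_spectrum(ax, R, channel = attr(spectra[[1]], "channel") %||% "main"),
    fluorescence = raman_spectrum(ax, Fv),
    fluorescence_penalized = raman_spectrum(ax, Fv - c0 - base),
    offsets = offsets,
    residual_norm = sqrt(sum((S - vapply(seq_len(m), function(i) {
      as.numeric(Tmats[[i]] %*% Fv) + R
    }, numeric(n)))^2)),
    iterations = it, converged = converged), class = "serds_result")
}

#' @export
print.serds_result <- function(x, ...) {
  cat(sprintf(
    "<serds_result: %d offsets spanning %.2f cm^-1, %d iterations, residual %.3g>\n",
    length(x$offsets), diff(range(x$offsets)), x$iterations,
    x$residual_norm))
  invisible(x)
}

#' Plot a SERDS separation
#' @param object a `serds_result`.
#' @param ... unused.
#' @return a ggplot object with the separated Raman and fluorescence
#'   components.
#' @method autoplot serds_result
#' @export
autoplot.serds_result <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(axis = object$raman$axis,
                   intensity = object$raman$intensity,
                   component = "Raman"),
    tibble::tibble(axis = object$fluorescence$axis,
                   intensity = object$fluorescence$intensity,
                   component = "Fluorescence"))
  ggplot2::ggplot(df, ggplot2::aes(.data$axis, .data$intensity,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(paste("Raman shift (", cm^-1, ")")),
                  y = "Intensity (a.u.)", color = NULL)
}
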