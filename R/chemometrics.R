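#' Assemble a calibration set
#'
#' Pairs preprocessed spectra (one per sample, common grid) with reference
#' concentrations for PLS calibration.
#'
#' @param spectra list of `raman_spectrum`s on a common grid, or a numeric
#'   matrix (rows = samples).
#' @param concentration numeric vector, one value per spectrum (any unit:
#'   vol%, g/L, uM).
#' @param replicate optional replicate ids.
#' @param unit concentration unit label.
#' @return a list of class `calibration_set` with matrix `X`, response `y`,
#'   `replicate`, `axis` and `unit`.
#' @export
calibration_set <- function(spectra, concentration, replicate = NULL,
                            unit = "") {
  if (is.list(spectra)) {
    axis <- spectra[[1]]$axis
    X <- t(vapply(spectra, function(s) {
      if (length(s$axis) != length(axis) || any(abs(s$axis - axis) > 1e-9)) {
        abort("spectra must share a common grid")
      }
      s$intensity
    }, numeric(length(axis))))
  } else {
    X <- as.matrix(spectra)
    axis <- seq_len(ncol(X))
  }
  if (nrow(X) != length(concentration)) {
    abort("one concentration per spectrum required")
  }
  structure(list(X = X, y = as.numeric(concentration),
                 replicate = replicate %||% seq_len(nrow(X)),
                 axis = axis, unit = unit),
            class = "calibration_set")
}

# NIPALS PLS1 with mean centering; returns scores/loadings/coefficients
pls1_nipals <- function(X, y, ncomp) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  n <- nrow(X)
  p <- ncol(X)
  ncomp <- min(ncomp, n - 1, p)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  Xa <- Xc
  ya <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xa, ya)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      ncomp <- a - 1L
      break
    }
    w <- w / nw
    t_ <- Xa %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) {
      ncomp <- a - 1L
      break
    }
    p_ <- crossprod(Xa, t_)[, 1] / tt
    q_ <- sum(ya * t_) / tt
    Xa <- Xa - t_ %*% t(p_)
    ya <- ya - q_ * t_
    W[, a] <- w
    P[, a] <- p_
    Q[a] <- q_
  }
  if (ncomp < 1) abort("degenerate calibration set: no usable component")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Q <- Q[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P, W), Q)
  list(x_center = xm, y_center = ym, W = W, P = P, Q = Q,
       coefficients = B[, 1], ncomp = ncomp)
}

#' Fit a PLS1 calibration model
#'
#' NIPALS partial least squares regression (PLS1, mean-centered) mapping
#' spectra to concentration. With `n_components = "auto"` the component
#' count minimizes the cross-validated RMSE under a one-standard-error
#' rule; cross-validation holds out all replicates of one concentration
#' level together, so replicate correlation cannot leak across folds.
#'
#' @param set a [calibration_set()].
#' @param n_components integer, or `"auto"`.
#' @param max_components search limit for `"auto"`.
#' @return a `pls_model`: centers, weights `W`, loadings `P`, regression
#'   vector `coefficients`, `ncomp`, the training axis and unit, and the
#'   cross-validation tibble `cv` (per component count).
#' @export
fit_pls <- function(set, n_components = "auto", max_components = 10) {
  X <- set$X
  y <- set$y
  if (nrow(X) < 3) abort("too few samples")
  if (stats::sd(y) == 0) abort("degenerate calibration set: constant response")
  a_max <- min(max_components, nrow(X) - 2, ncol(X))
  folds <- split(seq_along(y), factor(y))
  cv_err <- matrix(NA_real_, length(folds), a_max)
  for (f in seq_along(folds)) {
    idx <- folds[[f]]
    if (length(idx) == length(y)) next
    fit_a <- pls1_nipals(X[-idx, , drop = FALSE], y[-idx], a_max)
    for (a in seq_len(min(a_max, fit_a$ncomp))) {
      Ba <- fit_a$W[, 1:a, drop = FALSE] %*%
        solve(crossprod(fit_a$P[, 1:a, drop = FALSE],
                        fit_a$W[, 1:a, drop = FALSE]),
              fit_a$Q[1:a])
      pred <- fit_a$y_center +
        sweep(X[idx, , drop = FALSE], 2, fit_a$x_center) %*% Ba
      cv_err[f, a] <- mean((pred - y[idx])^2)
    }
  }
  cv_rmse <- sqrt(colMeans(cv_err, na.rm = TRUE))
  cv_se <- apply(cv_err, 2, function(e) {
    stats::sd(sqrt(e), na.rm = TRUE) / sqrt(sum(!is.na(e)))
  })
  if (identical(n_components, "auto")) {
    a_star <- which.min(cv_rmse)
    thresh <- cv_rmse[a_star] + cv_se[a_star]
    ncomp <- which(cv_rmse <= thresh)[1]
  } else {
    ncomp <- n_components
  }
  fit <- pls1_nipals(X, y, ncomp)
  structure(c(fit,
              list(axis = set$axis, unit = set$unit,
                   y_range = range(y), fitted = as.numeric(
                     fit$y_center + sweep(X, 2, fit$x_center) %*%
                       fit$coefficients),
                   y = y,
                   cv = tibble::tibble(ncomp = seq_len(a_max),
                                       cv_rmse = cv_rmse, cv_se = cv_se))),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model: %d components, train RMSE %.4g %s, CV RMSE %.4g>\n",
              x$ncomp, sqrt(mean((x$fitted - x$y)^2)), x$unit,
              x$cv$cv_rmse[x$ncomp]))
  invisible(x)
}

#' Predict concentrations from spectra
#'
#' @param object a `pls_model`.
#' @param newdata list of `raman_spectrum`s, a numeric matrix on the
#'   training grid, or a [calibration_set()].
#' @param ... unused.
#' @return a tibble with `.pred` and logical `.extrapolated` (prediction
#'   outside the training concentration range).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "calibration_set")) {
    if (length(newdata$axis) != length(object$axis) ||
        any(abs(newdata$axis - object$axis) > 1e-9)) {
      abort("grid mismatch between model and new spectra")
    }
    newdata$X
  } else if (is.list(newdata) && !is.data.frame(newdata)) {
    t(vapply(newdata, function(s) {
      if (length(s$axis) != length(object$axis) ||
          any(abs(s$axis - object$axis) > 1e-9)) {
        abort("grid mismatch between model and new spectra")
      }
      s$intensity
    }, numeric(length(object$axis))))
  } else {
    m <- as.matrix(newdata)
    if (ncol(m) != length(object$axis)) {
      abort("grid mismatch between model and new spectra")
    }
    m
  }
  pred <- as.numeric(object$y_center +
                       sweep(X, 2, object$x_center) %*% object$coefficients)
  tibble::tibble(.pred = pred,
                 .extrapolated = pred < object$y_range[1] |
                   pred > object$y_range[2])
}

#' Tidy and summarize a PLS model
#' @param x a `pls_model`.
#' @param ... unused.
#' @return `tidy()`: regression coefficient per axis point; `glance()`: a
#'   one-row model summary.
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  tibble::tibble(axis = x$axis, coefficient = x$coefficients)
}

#' @rdname tidy.pls_model
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp,
                 train_rmse = sqrt(mean((x$fitted - x$y)^2)),
                 cv_rmse = x$cv$cv_rmse[x$ncomp],
                 n = length(x$y))
}

#' Detection and quantification limits of a PLS calibration
#'
#' The 3-sigma / 10-sigma convention: `LoD = 3 * sd(predicted blanks) /
#' slope` and `LoQ = 10 * sd(predicted blanks) / slope`, with the slope
#' taken from a linear fit of predicted versus true concentration over the
#' low-concentration range (an accuracy correction: for an ideal
#' calibration the slope is 1).
#'
#' @param model a `pls_model`.
#' @param set the [calibration_set()]; must contain replicate blanks
#'   (concentration 0).
#' @param low_range upper bound of the low-concentration fit range;
#'   defaults to the median of the distinct levels.
#' @return a one-row tibble of class `detection_limits`: `slope`,
#'   `sigma_blank`, `lod`, `loq`, `formula` (`"3s/10s"`).
#' @export
detection_limits <- function(model, set, low_range = NULL) {
  pred <- predict(model, set)$.pred
  blanks <- set$y == 0
  if (sum(blanks) < 2) abort("replicate blanks (concentration 0) required")
  sigma_blank <- stats::sd(pred[blanks])
  if (is.null(low_range)) {
    low_range <- stats::median(unique(set$y))
  }
  low <- set$y <= low_range
  slope <- stats::coef(stats::lm(pred[low] ~ set$y[low]))[[2]]
  if (!is.finite(slope) || slope <= 0) abort("non-positive low-range slope")
  out <- tibble::tibble(slope = slope, sigma_blank = sigma_blank,
                        lod = 3 * sigma_blank / slope,
                        loq = 10 * sigma_blank / slope,
                        formula = "3s/10s", unit = set$unit)
  class(out) <- c("detection_limits", class(out))
  out
}

#' Average spectra from a mapping acquisition
#'
#' Pointwise mean over the unmasked map points; the mask excludes
#' saturated or failed-calibration points (SERS maps are heterogeneous, so
#' averaging over the chip surface is what gives a quantifiable signal).
#'
#' @param spectra list of `raman_spectrum`s on a common calibrated grid.
#' @param mask logical vector, TRUE = exclude the map point.
#' @return the mean `raman_spectrum` with attribute `n_used`.
#' @export
aggregate_map <- function(spectra, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(spectra))
  if (length(mask) != length(spectra)) abort("one mask entry per spectrum")
  keep <- which(!mask)
  if (!length(keep)) abort("all map points masked")
  ax <- spectra[[keep[1]]]$axis
  m <- rowMeans(vapply(spectra[keep], function(s) {
    if (length(s$axis) != length(ax) || any(abs(s$axis - ax) > 1e-9)) {
      abort("spectra must share a common grid")
    }
    s$intensity
  }, numeric(length(ax))))
  out <- spectrum_like(spectra[[keep[1]]], intensity = m)
  attr(out, "n_used") <- length(keep)
  out
}
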