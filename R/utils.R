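#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom ggplot2 autoplot
#' @importFrom dplyr %>%
NULL

#' @export
ggplot2::autoplot

#' @export
dplyr::`%>%`

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

rms <- function(x) sqrt(mean(x^2))

# Direct "same-size" convolution of a signal with a short kernel given the
# index (1-based) of the kernel's zero-offset tap. Edges are zero-padded.
conv_same <- function(x, k, k_center = (length(k) + 1L) %/% 2L) {
  n <- length(x)
  m <- length(k)
  out <- numeric(n)
  offsets <- seq_len(m) - k_center
  for (j in seq_len(m)) {
    o <- offsets[j]
    src <- seq_len(n) - o
    ok <- src >= 1L & src <= n
    out[ok] <- out[ok] + k[j] * x[src[ok]]
  }
  out
}

# FFT-based same-size convolution, zero-padded to avoid wrap-around.
fft_conv_same <- function(x, k, k_center = (length(k) + 1L) %/% 2L) {
  n <- length(x)
  m <- length(k)
  nfft <- stats::nextn(n + m, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  K <- stats::fft(c(k, numeric(nfft - m)))
  full <- Re(stats::fft(X * K, inverse = TRUE)) / nfft
  full[k_center:(k_center + n - 1L)]
}

# Deterministic polynomial hash of a string; stamps configs into manifests.
# Collision resistance is irrelevant here, only stability across runs.
config_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# run expr with a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
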