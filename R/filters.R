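#' Smoothed derivative estimation with Gaussian-derivative kernels
#'
#' Estimates the first or second time derivative of a uniformly sampled
#' signal by convolution with a derivative-of-Gaussian kernel
#' (Laplacian-of-Gaussian family).  Convolving with the kernel's derivative
#' is equivalent to differentiating the Gaussian-smoothed signal, which
#' keeps gradient estimates usable on noisy oculomotor velocity data where
#' finite differences would amplify sample noise.
#'
#' The kernel is normalised exactly on the discrete grid: a first-order
#' kernel returns slope `k` on the ramp `k*t`, a second-order kernel
#' returns `a` on the quadratic `a*t^2/2`, and both annihilate constants.
#' Edges are handled by reflection padding so the output has the same
#' length as the input.
#'
#' @param x numeric vector, uniformly sampled signal.
#' @param fs sampling rate in Hz.
#' @param sigma_ms Gaussian scale in milliseconds.
#' @param order derivative order, 1 (gradient) or 2 (curvature).
#' @return numeric vector of derivative estimates, in units of
#'   `x` per second (order 1) or per second squared (order 2).
#' @examples
#' t <- seq(0, 1, by = 1/250)
#' max(abs(log_gradient(3 * t, 250, 8))) # ~3
#' @export
log_gradient <- function(x, fs, sigma_ms = 8, order = 1) {
  stopifnot(is.numeric(x), fs > 0, sigma_ms > 0, order %in% c(1, 2))
  k <- gauss_deriv_kernel(fs, sigma_ms, order)
  half <- (length(k) - 1L) %/% 2L
  n <- length(x)
  if (n < length(k)) {
    vorsac_stop("vorsac_length_error", sprintf(
      "signal (%d samples) shorter than derivative kernel (%d samples)",
      n, length(k)))
  }
  xp <- c(x[(half + 1L):2L], x, x[(n - 1L):(n - half)])
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}

# Discrete Gaussian-derivative kernel.  stats::filter(x, k, sides = 2)
# computes y[i] = sum_j k[j] x(t_i - tk[j]) for a centred odd-length kernel,
# i.e. true convolution with the sampled continuous kernel.
gauss_deriv_kernel <- function(fs, sigma_ms, order) {
  sigma <- sigma_ms / 1000
  dt <- 1 / fs
  half <- max(2L, as.integer(ceiling(4 * sigma / dt)))
  tk <- seq.int(-half, half) * dt
  g <- exp(-tk^2 / (2 * sigma^2))
  if (order == 1) {
    k <- -tk / sigma^2 * g
    k <- k - mean(k)            # exact zero response to constants
    k / sum(-tk * k)            # exact unit response to unit ramp
  } else {
    k <- (tk^2 / sigma^4 - 1 / sigma^2) * g
    k <- k - mean(k)
    k / (sum(tk^2 * k) / 2)     # exact unit response to t^2/2
  }
}

#' Zero-phase first-order high-pass filter
#'
#' The operator written `f_HP` in the saccade cost function: a first-order
#' Butterworth high-pass applied forward and backward (zero phase lag).
#' Applied to the fit residual it suppresses the slow, low-frequency VOR
#' component so that only the fast saccadic transient drives the fit.
#'
#' The recursion is run directly with [stats::filter()] (zero initial
#' state); coefficient design comes from [signal::butter()].
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz corner frequency (Hz), default 3.
#' @return filtered vector, same length as `x`.
#' @export
hp_filter <- function(x, fs, cutoff_hz = 3) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2)
  ba <- butter_hp_coefs(fs, cutoff_hz)
  # Subtracting the leading sample before each pass removes the step
  # transient of the zero-state recursion, so constants map to exactly 0.
  fwd <- iir1(x - x[1], ba$b, ba$a)
  bwd <- rev(fwd)
  rev(iir1(bwd - bwd[1], ba$b, ba$a))
}

# One-pole IIR pass, C-level via stats::filter.
iir1 <- function(x, b, a) {
  num <- b[1] * x + b[2] * c(0, x[-length(x)])
  as.numeric(stats::filter(num, -a[2], method = "recursive"))
}

.butter_cache <- new.env(parent = emptyenv())
butter_hp_coefs <- function(fs, cutoff_hz) {
  key <- sprintf("%g_%g", fs, cutoff_hz)
  if (is.null(.butter_cache[[key]])) {
    bf <- signal::butter(1, cutoff_hz / (fs / 2), type = "high")
    .butter_cache[[key]] <- list(b = as.numeric(bf$b), a = as.numeric(bf$a))
  }
  .butter_cache[[key]]
}
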