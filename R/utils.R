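# Internal helpers shared across modules.

# Classed error constructor so callers can discriminate rejection reasons
# (per-trial rejections are recoverable; I/O and validation errors are not).
vorsac_stop <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "vorsac_error", "error", "condition"),
    c(list(message = msg, call = NULL), extra)
  )
  stop(cond)
}

# Parabolic (three-point) refinement of an extremum located at index i of y
# sampled on a uniform grid t.  Returns c(t_hat, y_hat).  Falls back to the
# grid point at the edges or for degenerate curvature.
refine_peak <- function(t, y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(c(t[i], y[i]))
  y0 <- y[i - 1L]; y1 <- y[i]; y2 <- y[i + 1L]
  denom <- y0 - 2 * y1 + y2
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps * 100) {
    return(c(t[i], y[i]))
  }
  delta <- 0.5 * (y0 - y2) / denom
  delta <- max(min(delta, 1), -1)
  dt <- t[2] - t[1]
  c(t[i] + delta * dt, y1 - 0.25 * (y0 - y2) * delta)
}

# Linear interpolation of y(t) at a single point (t uniform, ascending).
interp_at <- function(t, y, t0) {
  stats::approx(t, y, xout = t0, rule = 2)$y
}

# Trapezoidal integral of y over [a, b] (same units as t), with linearly
# interpolated endpoint values so the window need not align with samples.
trapz_window <- function(t, y, a, b) {
  if (b <= a) return(0)
  inside <- which(t > a & t < b)
  tt <- c(a, t[inside], b)
  yy <- c(interp_at(t, y, a), y[inside], interp_at(t, y, b))
  pracma::trapz(tt, yy)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
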