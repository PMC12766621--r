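`%||%` <- function(a, b) if (is.null(a)) b else a

frame_mean <- function(frames, idx) {
  if (length(idx) == 1L) frames[, , idx] else apply(frames[, , idx, drop = FALSE], c(1, 2), mean)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

# Linear interpolation treating the curve as 0 before its first sample and
# held at its last value after the end (causal inputs start at 0 anyway).
interp_curve <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2, yleft = 0, ties = "ordered")$y
}

# Uniform internal grid for convolution work on possibly non-uniform trigger
# grids. dt defaults to half the median sampling interval.
uniform_grid <- function(times, oversample = 2) {
  dt <- stats::median(diff(times)) / oversample
  seq(times[1], times[length(times)], by = dt)
}

# Causal convolution (f * g)(t) on a uniform grid by trapezoidal quadrature.
conv_uniform <- function(f, g, dt) {
  n <- length(f)
  full <- stats::convolve(f, rev(g), type = "open")[seq_len(n)]
  # trapezoid end-correction of the Riemann sum
  (full - 0.5 * f[1] * g - 0.5 * f * g[1]) * dt
}

# Exact convolution of exp(rate * t) (rate <= 0) with a piecewise-linear
# input on a uniform grid; vectorized over a vector of rates. Returns a
# matrix [time, rate].
conv_exp <- function(ca, dt, rates) {
  n <- length(ca)
  m <- length(rates)
  z <- rates * dt
  ez <- exp(z)
  small <- abs(z) < 1e-8
  # E1 = int_0^dt e^{r s} ds,  E2 = int_0^dt s e^{r s} ds
  E1 <- ifelse(small, dt * (1 + z / 2), (ez - 1) / rates)
  E2 <- ifelse(small, dt^2 * (0.5 + z / 3), (dt * ez - E1) / rates)
  out <- matrix(0, n, m)
  y <- numeric(m)
  for (i in 2:n) {
    slope <- (ca[i] - ca[i - 1]) / dt
    y <- y * ez + ca[i] * E1 - slope * E2
    out[i, ] <- y
  }
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear translation of an image by v = c(dx, dy) pixels (content moves by
# +v), zero-filled at the borders.
shift_image <- function(img, v) {
  EBImage::translate(img, v, filter = "bilinear", bg.col = 0)
}

is_dynamic_series <- function(x) inherits(x, "dynamic_series")

stop_if_not_series <- function(x) {
  if (!is_dynamic_series(x)) stop("expected a dynamic_series object")
  invisible(x)
}
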