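# Internal numerical helpers shared across modules.

#' Wrap an angle to (-pi, pi]
#' @param x angle(s) in radians.
#' @return wrapped angle(s).
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Unwrap a phase series
#'
#' Removes 2*pi jumps from a sampled angle series so that it becomes
#' continuous, like `numpy.unwrap`.
#' @param x angle series (radians).
#' @return unwrapped series.
#' @keywords internal
unwrap_angle <- function(x) {
  if (length(x) < 2L) return(x)
  d <- diff(x)
  jumps <- -2 * pi * round(d / (2 * pi))
  x + c(0, cumsum(jumps))
}

# Trapezoid integral of y over grid x (vector or column-wise for a matrix).
trapz <- function(x, y) {
  n <- length(x)
  if (is.matrix(y)) {
    colSums((y[-1, , drop = FALSE] + y[-n, , drop = FALSE]) / 2 * diff(x))
  } else {
    sum((y[-1] + y[-n]) / 2 * diff(x))
  }
}

# Cumulative trapezoid integral along a vector (first element 0).
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

# Trapezoid quadrature weights for a (possibly nonuniform) grid.
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(1, n))
  d <- diff(x)
  c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}

#' Gaussian smoothing of a regularly sampled series
#'
#' Convolution with a Gaussian kernel of standard deviation `sd_s` seconds,
#' truncated at +/- 3 SD.  Edges are handled by renormalising the kernel over
#' the available samples, so the filter is unbiased for a locally constant
#' signal up to the boundary.
#'
#' @param x numeric series sampled at interval `dt`.
#' @param dt sampling interval (s).
#' @param sd_s kernel standard deviation (s).
#' @return smoothed series, same length as `x`.
#' @keywords internal
gaussian_smooth <- function(x, dt, sd_s) {
  if (sd_s <= 0) return(x)
  half <- max(1L, ceiling(3 * sd_s / dt))
  k <- stats::dnorm(seq(-half, half) * dt, sd = sd_s)
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
}

# Central-difference derivative on a uniform grid (one-sided at the ends).
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) stop("need at least two samples for a derivative")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2L) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d
}

# 2x2 rotation matrix.
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}
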