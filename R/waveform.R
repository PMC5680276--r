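# Synthetic two-harmonic curvature waveforms and random-curvature nulls.
#
# The tethered-sperm beat is modelled as a curvature wave
#   C(s, t) = C0 + C1 sin(k s - w0 t) + C2(t) sin(k s - 2 w0 t + phi(t)),
# a fundamental traveling wave plus its second harmonic sharing the same
# wavenumber k, with an optional static curvature offset C0.  Amplitude and
# phase of the second harmonic may drift slowly, emulating the slow variation
# of rotation velocity seen in recordings.

#' Two-harmonic waveform specification
#'
#' Parameters of the curvature-space beat waveform.  Units are micrometres,
#' seconds and 1/micrometres for curvature throughout the package; reported
#' frequencies are in Hz while `omega0` is angular (rad/s).
#'
#' @param C1 fundamental curvature amplitude (1/um), >= 0.
#' @param C2 second-harmonic curvature amplitude (1/um), >= 0.
#' @param C0 static curvature offset (1/um).
#' @param f0 fundamental beat frequency (Hz); `omega0 = 2*pi*f0`.
#' @param lambda wavelength of the traveling wave (um); `k = 2*pi/lambda`.
#' @param phi phase shift of the second harmonic relative to the fundamental
#'   (rad); wrapped to (-pi, pi].
#' @param L flagellar length (um).
#' @return an object of class `waveform_spec`.  The small-amplitude transverse
#'   displacement amplitudes `y1 = C1/k^2`, `y2 = C2/k^2` (um) are included
#'   for use with the small-amplitude closed forms.
#' @export
#' @examples
#' waveform_spec(C1 = 0.1, C2 = 0.02, f0 = 20, lambda = 40, phi = pi / 2)
waveform_spec <- function(C1, C2 = 0, C0 = 0, f0 = 20, lambda = 40,
                          phi = 0, L = 40) {
  stopifnot(C1 >= 0, C2 >= 0, L > 0, lambda > 0, f0 > 0)
  k <- 2 * pi / lambda
  structure(list(
    C0 = C0, C1 = C1, C2 = C2,
    k = k, lambda = lambda,
    omega0 = 2 * pi * f0, f0 = f0,
    phi = wrap_angle(phi), L = L,
    y1 = C1 / k^2, y2 = C2 / k^2
  ), class = "waveform_spec")
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat("Two-harmonic waveform spec\n")
  cat(sprintf("  C0 = %g, C1 = %g, C2 = %g 1/um  (C2/C1 = %.3g)\n",
              x$C0, x$C1, x$C2, ifelse(x$C1 > 0, x$C2 / x$C1, NA)))
  cat(sprintf("  f0 = %g Hz, lambda = %g um, phi = %.3f rad, L = %g um\n",
              x$f0, x$lambda, x$phi, x$L))
  invisible(x)
}

#' Slow drift of second-harmonic amplitude and phase
#'
#' Describes how `C2(t)`, `phi(t)` and optionally `C0(t)` vary over a
#' recording.  Either supply functions of time directly, or use
#' [random_drift()] to draw a smoothed Gaussian random walk.  Drift must be
#' slow compared with the beat period for the windowed harmonic analysis to
#' be meaningful.
#'
#' @param C2_fun function of time t (s) returning the second-harmonic
#'   amplitude (1/um); values are clamped at zero.
#' @param phi_fun function of time returning the second-harmonic phase (rad).
#' @param C0_fun optional function of time returning the curvature offset;
#'   `NULL` keeps the spec's static `C0`.
#' @param noise_sd standard deviation of additive white curvature noise
#'   (1/um) applied per grid point.
#' @param tau_corr nominal drift correlation time (s), recorded for reference.
#' @return an object of class `drift_profile`.
#' @export
drift_profile <- function(C2_fun = NULL, phi_fun = NULL, C0_fun = NULL,
                          noise_sd = 0, tau_corr = 2) {
  stopifnot(noise_sd >= 0, tau_corr > 0)
  structure(list(C2_fun = C2_fun, phi_fun = phi_fun, C0_fun = C0_fun,
                 noise_sd = noise_sd, tau_corr = tau_corr),
            class = "drift_profile")
}

#' Smoothed Gaussian random-walk drift
#'
#' Draws independent smoothed Gaussian random walks for the second-harmonic
#' amplitude and phase (and optionally the curvature offset).  A white
#' Gaussian series on the time grid is filtered with a Gaussian kernel of
#' standard deviation `tau_corr`, scaled to the requested stationary SD and
#' offset by the requested mean.  The default 2 s correlation time makes the
#' drift slow compared with a 50 ms beat period, reproducing rotation
#' velocities that vary smoothly over seconds.
#'
#' @param t time grid (s) on which the drift will be evaluated.
#' @param C2_mean,C2_sd mean and SD of the second-harmonic amplitude (1/um).
#' @param phi_mean,phi_sd mean and SD of the second-harmonic phase (rad).
#' @param C0_mean,C0_sd mean and SD of the curvature offset; both zero keeps
#'   the offset static.
#' @param noise_sd additive white curvature noise SD (1/um).
#' @param tau_corr drift correlation time (s).
#' @param seed integer RNG seed.
#' @return a `drift_profile` whose component functions interpolate the drawn
#'   walks (constant extrapolation beyond `range(t)`).
#' @export
random_drift <- function(t, C2_mean = 0.015, C2_sd = 0.005,
                         phi_mean = 0.8, phi_sd = 0.6,
                         C0_mean = 0, C0_sd = 0,
                         noise_sd = 0, tau_corr = 2, seed = 1) {
  dt <- t[2] - t[1]
  walk <- function(mean, sd) {
    if (sd == 0) {
      f <- function(tt) rep(mean, length(tt))
      return(f)
    }
    z <- gaussian_smooth(stats::rnorm(length(t)), dt, tau_corr)
    z <- (z - mean(z)) / stats::sd(z) * sd + mean
    stats::approxfun(t, z, rule = 2)
  }
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  C2f <- walk(C2_mean, C2_sd)
  phif <- walk(phi_mean, phi_sd)
  C0f <- if (C0_sd > 0 || C0_mean != 0) walk(C0_mean, C0_sd) else NULL
  drift_profile(C2_fun = function(tt) pmax(0, C2f(tt)), phi_fun = phif,
                C0_fun = C0f, noise_sd = noise_sd, tau_corr = tau_corr)
}

# Seed hygiene: run a block under a given seed and restore the global state.
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a two-harmonic curvature field
#'
#' Evaluates the curvature wave on an arclength/time grid, with optional slow
#' drift of the second-harmonic parameters and additive tracking noise.  The
#' returned field carries a `truth` attribute (a `ground_truth` record) that
#' fully determines the dataset given the seed.
#'
#' @param spec a [waveform_spec()].
#' @param drift a [drift_profile()] or `NULL` for constant parameters.
#' @param s arclength grid (um); default `seq(0, spec$L, by = 0.9)`.
#' @param t time grid (s); must span at least two beat periods.
#' @param seed integer RNG seed for the noise.
#' @return a [curvature_field] (arclength x time matrix with grids), with the
#'   generating parameters in `attr(, "truth")`.
#' @export
#' @examples
#' spec <- waveform_spec(C1 = 0.1, C2 = 0.03, f0 = 20, lambda = 40)
#' cf <- gen_curvature_wave(spec, t = seq(0, 0.5, by = 1 / 500))
#' dim(cf$C)
gen_curvature_wave <- function(spec, drift = NULL,
                               s = seq(0, spec$L, by = 0.9),
                               t = seq(0, 10, by = 1 / 500),
                               seed = 1) {
  stopifnot(inherits(spec, "waveform_spec"))
  if (any(diff(s) <= 0) || any(diff(t) <= 0)) {
    stop("grids must be strictly increasing")
  }
  period <- 1 / spec$f0
  if (diff(range(t)) < period) {
    stop("time grid shorter than one beat period: harmonic analysis undefined")
  }
  C2t <- if (!is.null(drift) && !is.null(drift$C2_fun)) drift$C2_fun(t) else rep(spec$C2, length(t))
  phit <- if (!is.null(drift) && !is.null(drift$phi_fun)) drift$phi_fun(t) else rep(spec$phi, length(t))
  C0t <- if (!is.null(drift) && !is.null(drift$C0_fun)) drift$C0_fun(t) else rep(spec$C0, length(t))
  ph1 <- outer(spec$k * s, spec$omega0 * t, `-`)          # k s - w0 t
  ph2 <- sweep(outer(spec$k * s, 2 * spec$omega0 * t, `-`), 2, phit, `+`)
  C <- sweep(spec$C1 * sin(ph1) + sweep(sin(ph2), 2, C2t, `*`), 2, C0t, `+`)
  noise_sd <- if (!is.null(drift)) drift$noise_sd else 0
  if (noise_sd > 0) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
    C <- C + matrix(stats::rnorm(length(C), sd = noise_sd), nrow(C), ncol(C))
  }
  cf <- curvature_field(C, s, t)
  attr(cf, "truth") <- structure(list(
    spec = spec, C2_t = C2t, phi_t = phit, C0_t = C0t,
    noise_sd = noise_sd, seed = seed
  ), class = "ground_truth")
  cf
}

#' Random delta-correlated curvature field
#'
#' White Gaussian curvature noise with per-entry standard deviation `sigma`,
#' the significance null for the principal-component mode analysis.
#'
#' @param sigma curvature SD (1/um), > 0.
#' @param s,t arclength and time grids.
#' @param seed integer RNG seed; identical seeds give bitwise-identical
#'   fields.
#' @return a [curvature_field].
#' @export
gen_random_curvature <- function(sigma, s, t, seed = 1) {
  stopifnot(sigma > 0)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  C <- matrix(stats::rnorm(length(s) * length(t), sd = sigma),
              length(s), length(t))
  cf <- curvature_field(C, s, t)
  attr(cf, "truth") <- structure(list(sigma = sigma, seed = seed),
                                 class = "ground_truth")
  cf
}
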