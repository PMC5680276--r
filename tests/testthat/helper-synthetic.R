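# Shared fixtures: small, fast synthetic datasets built in code.

# reference two-harmonic waveform (experimental scale)
ref_spec <- function(C2 = 0.03, phi = 0.5, C0 = 0) {
  waveform_spec(C1 = 0.1, C2 = C2, C0 = C0, f0 = 20, lambda = 40, phi = phi,
                L = 40)
}

# short clean curvature field (2 s at 500 fps, ~40 arclength points)
ref_field <- function(spec = ref_spec(), noise_sd = 0, seconds = 2, seed = 1) {
  drift <- if (noise_sd > 0) drift_profile(noise_sd = noise_sd) else NULL
  gen_curvature_wave(spec, drift, s = seq(0, 36, by = 0.9),
                     t = seq(0, seconds, by = 1 / 500), seed = seed)
}

# small tethered-cell scene for tracking tests
ref_scene <- function(seconds = 0.2, snr = 20, omega = 0.05, seed = 2) {
  spec <- ref_spec(C2 = 0.015, phi = 0.8)
  tracks <- gen_rotating_cell(spec, NULL, omega_fun = omega,
                              s = seq(0, 36, by = 0.9),
                              t = seq(0, seconds, by = 1 / 500),
                              skip_points = 3, seed = seed)
  render_frames(tracks, pixel_um = 0.5, snr = snr, seed = seed + 1)
}

# root-mean-square distance from estimated points to the continuous true
# midline (densely interpolated), averaged over a subsample of frames.
# Tracked points sample the curve at their own arclength phase, so distance
# to the curve -- not to the truth's nodes -- is the accuracy measure.
tracks_rmse <- function(est, truth, every = 5) {
  a <- flagbeat:::tracks_arrays(est)
  b <- flagbeat:::tracks_arrays(truth)
  frames <- seq(1, ncol(a$x), by = every)
  mean(vapply(frames, function(f) {
    cum <- c(0, cumsum(sqrt(diff(b$x[, f])^2 + diff(b$y[, f])^2)))
    dense <- seq(0, max(cum), by = 0.05)
    bx <- stats::spline(cum, b$x[, f], xout = dense)$y
    by <- stats::spline(cum, b$y[, f], xout = dense)$y
    d <- vapply(seq_len(nrow(a$x)), function(i) {
      min(sqrt((bx - a$x[i, f])^2 + (by - a$y[i, f])^2))
    }, numeric(1))
    sqrt(mean(d^2))
  }, numeric(1)))
}

circular_mean <- function(x) Arg(mean(exp(1i * x)))
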