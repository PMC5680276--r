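# Time-resolved harmonic analysis of the curvature at a fixed arclength:
# fundamental frequency, amplitudes C1 and C2, the relative phase phi of the
# second harmonic, and the correlation of the second-harmonic intensity
# C2 sin(phi + phi0) with the normalised rotation velocity Omega/omega0.

#' Windowed harmonic trace of a curvature time series
#'
#' A plain (rectangular-window) discrete Fourier transform is evaluated every
#' `step` frames over a sliding window of `W` frames.  Per window the
#' fundamental peak is located in `band` (with parabolic interpolation on the
#' log-spectrum for sub-bin resolution), and the complex amplitudes at the
#' fundamental and at twice the fundamental are read off by direct harmonic
#' projection at the interpolated frequency, referenced to absolute time.
#' Amplitudes are debiased for the noise power collected by the projection,
#' estimated from the local spectral floor at nearby frequencies.
#'
#' Writing the signal as
#' `C(t) = C1 sin(a1 - w0 t) + C2 sin(a2 - 2 w0 t)`, the relative phase is
#' `phi = a2 - a1`, which for a traveling wave whose harmonics share one
#' wavenumber is independent of the probe arclength.  In terms of the
#' projected complex amplitudes it is `phi = Arg(A1) - Arg(A2)`, so a signal
#' synthesised from a [waveform_spec()] returns its own `phi`.
#'
#' @param x curvature time series at one arclength (1/um), or a
#'   [curvature_field] together with `s0`.
#' @param frame_rate frames per second.
#' @param W window width (frames).
#' @param step hop between window centres (frames).
#' @param band fundamental search band (Hz).
#' @param s0 probe arclength (um), used when `x` is a curvature field: the
#'   row nearest `s0` is analysed.
#' @param t0 absolute time (s) of the first sample.  The phase convention
#'   references both harmonics to absolute time, so `phi` is invariant only
#'   under time-origin shifts by whole fundamental periods; supply `t0` when
#'   analysing a slice of a longer record.  Taken from a curvature field's
#'   time axis automatically.
#' @param noise_floor windows whose fundamental peak does not exceed
#'   `noise_floor` times the median in-band spectral amplitude are masked
#'   (NA).
#' @return an object of class `harmonic_trace`: data.frame with columns `t`
#'   (window centre, s), `f0` (Hz), `C1`, `C2` (1/um), `phi` (rad, wrapped);
#'   attributes `W`, `step`, `frame_rate`, `s0`.
#' @export
spectrogram_harmonics <- function(x, frame_rate = 500, W = 250, step = 30,
                                  band = c(10, 35), s0 = NULL,
                                  noise_floor = 3, t0 = 0) {
  if (inherits(x, "curvature_field")) {
    if (is.null(s0)) s0 <- stats::median(x$s)
    row <- which.min(abs(x$s - s0))
    frame_rate <- 1 / x$dt
    t0 <- x$t[1]
    x <- x$C[row, ]
  }
  n <- length(x)
  if (n < W) stop("record shorter than one analysis window")
  if (2 * band[2] >= frame_rate / 2) {
    stop("second harmonic of the band is not resolvable at this frame rate")
  }
  peak_freq <- function(seg) {
    m <- length(seg)
    sp <- stats::fft(seg - mean(seg))
    fg <- (0:(m - 1)) * frame_rate / m
    bi <- which(fg >= band[1] & fg <= band[2])
    amp <- Mod(sp[bi])
    pk <- which.max(amp)
    if (amp[pk] < noise_floor * stats::median(amp)) return(NA_real_)
    j <- bi[pk]
    delta <- 0
    if (pk > 1 && pk < length(bi)) {
      la <- log(pmax(Mod(sp[c(j - 1, j, j + 1)]), 1e-300))
      den <- la[1] - 2 * la[2] + la[3]
      if (den < 0) delta <- max(-0.5, min(0.5, 0.5 * (la[1] - la[3]) / den))
    }
    (j - 1 + delta) * frame_rate / m
  }
  # one high-resolution reference frequency for the whole record: the phase
  # convention phi = Arg(A1) - Arg(A2) references both harmonics to absolute
  # time, so the frequency error must satisfy df << 1/(2 pi T_record)
  f_ref <- peak_freq(x)
  if (!is.finite(f_ref)) stop("no fundamental peak above the noise floor")
  tt_all <- t0 + (seq_len(n) - 1) / frame_rate
  xz <- x - mean(x)
  df <- frame_rate / n
  f_ref <- stats::optimize(function(f) Mod(sum(xz * exp(-2i * pi * f * tt_all))),
                           c(f_ref - df, f_ref + df), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)$maximum
  centers <- seq(ceiling(W / 2), n - floor(W / 2), by = step)
  res <- vapply(centers, function(ic) {
    idx <- (ic - ceiling(W / 2) + 1):(ic + floor(W / 2))
    seg <- x[idx]
    seg <- seg - mean(seg)
    f0 <- peak_freq(seg)
    if (!is.finite(f0)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    tt <- t0 + (idx - 1) / frame_rate   # absolute time of the samples
    proj <- function(f) 2 * mean(seg * exp(-2i * pi * f * tt))
    A1 <- proj(f0)                      # amplitudes at the local peak
    A2 <- proj(2 * f0)
    # debias |A| for the noise power the projection picks up, measured as
    # the local spectral floor: projections at nearby signal-free
    # frequencies have expectation equal to the noise contribution
    off <- c(-8:-3, 3:8) * frame_rate / length(seg)
    floor_at <- function(f) mean(vapply(f + off,
                                        function(ff) Mod(proj(ff))^2,
                                        numeric(1)))
    C1a <- sqrt(max(Mod(A1)^2 - floor_at(f0), 0))
    C2a <- sqrt(max(Mod(A2)^2 - floor_at(2 * f0), 0))
    phi <- wrap_angle(Arg(proj(f_ref)) - Arg(proj(2 * f_ref)))
    c(f0, C1a, C2a, phi)
  }, numeric(4))
  out <- data.frame(t = t0 + (centers - 1) / frame_rate,
                    f0 = res[1, ], C1 = res[2, ], C2 = res[3, ],
                    phi = res[4, ])
  structure(out, W = W, step = step, frame_rate = frame_rate, s0 = s0,
            class = c("harmonic_trace", "data.frame"))
}

#' @export
print.harmonic_trace <- function(x, ...) {
  ok <- is.finite(x$f0)
  cat(sprintf("Harmonic trace: %d windows (%d masked)\n", nrow(x), sum(!ok)))
  if (any(ok)) {
    cat(sprintf("  f0 = %.2f +/- %.2f Hz,  C1 = %.4g,  C2 = %.4g 1/um,  C2/C1 = %.3g\n",
                mean(x$f0[ok]), stats::sd(x$f0[ok]), mean(x$C1[ok]),
                mean(x$C2[ok]), mean(x$C2[ok] / x$C1[ok])))
    cat(sprintf("  phi (circular mean) = %.3f rad\n",
                Arg(mean(exp(1i * x$phi[ok])))))
  }
  invisible(x)
}

#' Second-harmonic intensity
#'
#' The steering-relevant combination `I(t) = C2(t) sin(phi(t) + phi0)`: the
#' component of the second harmonic that breaks the beat's temporal mirror
#' symmetry in the direction that produces net torque.
#'
#' @param trace a `harmonic_trace`.
#' @param phi0 constant phase offset (rad).
#' @return numeric vector, same length as the trace (1/um).
#' @export
second_harmonic_intensity <- function(trace, phi0 = 0) {
  trace$C2 * sin(trace$phi + phi0)
}

# Resample a rotation trace onto harmonic-trace window centres and return the
# paired, finite, normalised series used by the steering correlation.
steering_pairs <- function(rotation, trace) {
  Om <- stats::approx(rotation$t, rotation$Omega, xout = trace$t, rule = 2)$y
  u <- Om / trace$f0                     # both in cycles/s, dimensionless
  ok <- is.finite(u) & is.finite(trace$C2) & is.finite(trace$phi)
  list(u = u[ok], C2 = trace$C2[ok], phi = trace$phi[ok], n = sum(ok))
}

#' Steering correlation between rotation and second-harmonic intensity
#'
#' Non-centred correlation between the normalised rotation velocity
#' `Omega(t)/omega0(t)` and the second-harmonic intensity
#' `I(t) = C2(t) sin(phi(t) + phi0)`:
#' `R = <u I> / sqrt(<u^2> <I^2>)`.
#' Both series are taken about zero rather than about their means, matching
#' the expectation that without a second harmonic there is no rotation.
#'
#' @param rotation a `rotation_trace` (see [rotation_velocity()]) or a
#'   data.frame with columns `t` and `Omega` (rev/s).
#' @param trace a `harmonic_trace`.
#' @param phi0 constant phase offset (rad).
#' @return scalar correlation in `[-1, 1]`.
#' @export
correlation_R <- function(rotation, trace, phi0 = 0) {
  p <- steering_pairs(rotation, trace)
  I <- p$C2 * sin(p$phi + phi0)
  if (all(p$u == 0) || all(I == 0)) {
    stop("correlation undefined: a series is identically zero")
  }
  mean(p$u * I) / sqrt(mean(p$u^2) * mean(I^2))
}

#' Optimal phase offset for the steering correlation
#'
#' Chooses the single constant `phi0` per recording that maximises
#' [correlation_R()].  A closed-form initial guess comes from the numerator
#' quadratures `<u C2 sin phi>` and `<u C2 cos phi>`; a 1-degree grid over
#' (-pi, pi] followed by golden-section refinement handles the phi0
#' dependence of the denominator.
#'
#' @inheritParams correlation_R
#' @param grid_deg grid resolution (degrees).
#' @return list with `phi0` (rad), `R_max`, and `identifiable` (FALSE when
#'   the objective is flat to within 1e-3, in which case a warning is
#'   raised).
#' @export
optimize_phase_offset <- function(rotation, trace, grid_deg = 1) {
  p <- steering_pairs(rotation, trace)
  if (p$n < 50) stop("need at least 50 common time points")
  Rof <- function(phi0) {
    I <- p$C2 * sin(p$phi + phi0)
    mean(p$u * I) / sqrt(mean(p$u^2) * mean(I^2))
  }
  grid <- seq(-pi, pi, by = grid_deg * pi / 180)
  vals <- vapply(grid, Rof, numeric(1))
  if (diff(range(vals, na.rm = TRUE)) < 1e-3) {
    warning("phase unidentifiable: correlation objective is flat")
    return(list(phi0 = NA_real_, R_max = max(vals, na.rm = TRUE),
                identifiable = FALSE))
  }
  i <- which.max(vals)
  lo <- grid[i] - grid_deg * pi / 180
  hi <- grid[i] + grid_deg * pi / 180
  opt <- stats::optimize(Rof, c(lo, hi), maximum = TRUE, tol = 1e-6)
  list(phi0 = wrap_angle(opt$maximum), R_max = opt$objective,
       identifiable = TRUE)
}

#' Probe-consistency of the steering correlation
#'
#' Re-estimates the steering correlation from the curvature at several probe
#' arclengths, holding the phase offset fixed at the value optimised for the
#' reference probe.  Because the two harmonics of a traveling wave share one
#' wavenumber, the relative phase — and hence R — should be nearly
#' independent of the probe position.
#'
#' @param field a [curvature_field].
#' @param rotation a `rotation_trace`.
#' @param s_list probe arclengths (um).
#' @param s_ref reference probe (um); defaults to the last entry of
#'   `s_list`.
#' @param ... passed to [spectrogram_harmonics()].
#' @return data.frame with columns `s0`, `R`, `delta_R` (difference from the
#'   reference probe's R), and attribute `phi0`.
#' @export
probe_consistency <- function(field, rotation, s_list = c(15, 25),
                              s_ref = NULL, ...) {
  if (is.null(s_ref)) s_ref <- s_list[length(s_list)]
  tr_ref <- spectrogram_harmonics(field, s0 = s_ref, ...)
  opt <- optimize_phase_offset(rotation, tr_ref)
  R <- vapply(s_list, function(s0) {
    tr <- spectrogram_harmonics(field, s0 = s0, ...)
    correlation_R(rotation, tr, opt$phi0)
  }, numeric(1))
  R_ref <- correlation_R(rotation, tr_ref, opt$phi0)
  out <- data.frame(s0 = s_list, R = R, delta_R = R - R_ref)
  attr(out, "phi0") <- opt$phi0
  out
}
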