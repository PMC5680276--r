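# Spectrogram harmonic estimation and the steering correlation.

test_that("a pure sinusoid is recovered with a clean second-harmonic floor", {
  cf <- gen_curvature_wave(waveform_spec(C1 = 0.08, C2 = 0, f0 = 20,
                                         lambda = 40),
                           t = seq(0, 4, by = 1 / 500))
  tr <- spectrogram_harmonics(cf, s0 = 15)
  ok <- is.finite(tr$f0)
  expect_equal(mean(tr$f0[ok]), 20, tolerance = 0.5 / 20)
  expect_equal(mean(tr$C1[ok]), 0.08, tolerance = 0.03)
  expect_lt(mean(tr$C2[ok]) / mean(tr$C1[ok]), 0.01)
})

test_that("two-harmonic amplitude and phase are recovered at any probe", {
  for (phi in c(-1.2, 0, 1.0)) {
    cf <- gen_curvature_wave(ref_spec(C2 = 0.015, phi = phi),
                             t = seq(0, 5, by = 1 / 500))
    for (s0 in c(15, 25)) {
      tr <- spectrogram_harmonics(cf, s0 = s0)
      ok <- is.finite(tr$f0)
      expect_equal(mean(tr$C2[ok]), 0.015, tolerance = 0.05)
      expect_lt(abs(flagbeat:::wrap_angle(circular_mean(tr$phi[ok]) - phi)),
                0.1)
    }
  }
})

test_that("a linear chirp is tracked within one bin per window", {
  fs <- 500
  t <- seq(0, 6, by = 1 / fs)
  f_inst <- 16 + 2 * t                    # 16 -> 28 Hz
  phase <- 2 * pi * cumsum(f_inst) / fs
  x <- 0.1 * sin(phase)
  tr <- spectrogram_harmonics(x, frame_rate = fs, W = 250, step = 30)
  ok <- is.finite(tr$f0)
  bin <- fs / 250
  expect_lt(max(abs(tr$f0[ok] - (16 + 2 * tr$t[ok]))), bin)
})

test_that("amplitudes are linear in the signal and phase is shift-stable", {
  cf <- gen_curvature_wave(ref_spec(C2 = 0.02, phi = 0.7),
                           t = seq(0, 3, by = 1 / 500))
  tr1 <- spectrogram_harmonics(cf, s0 = 15)
  cf2 <- cf; cf2$C <- 2 * cf$C
  tr2 <- spectrogram_harmonics(cf2, s0 = 15)
  ok <- is.finite(tr1$f0) & is.finite(tr2$f0)
  expect_equal(tr2$C1[ok], 2 * tr1$C1[ok], tolerance = 1e-6)
  expect_equal(tr2$C2[ok], 2 * tr1$C2[ok], tolerance = 1e-6)
  expect_equal(tr2$phi[ok], tr1$phi[ok], tolerance = 1e-6)
  # shifting the time origin by whole fundamental periods leaves phi fixed
  row <- which.min(abs(cf$s - 15))
  x <- cf$C[row, ]
  tr3 <- spectrogram_harmonics(x[-(1:25)], frame_rate = 500)  # one period
  ok3 <- is.finite(tr3$f0)
  expect_lt(abs(flagbeat:::wrap_angle(circular_mean(tr3$phi[ok3]) -
                                      circular_mean(tr1$phi[ok]))), 0.02)
})

test_that("second-harmonic intensity follows C2 sin(phi + phi0)", {
  tr <- structure(data.frame(t = 1:5, f0 = 20, C1 = 0.1,
                             C2 = c(1, 2, 3, 4, 5) / 100,
                             phi = c(0, pi / 2, -pi / 2, 0.3, -0.3)),
                  class = c("harmonic_trace", "data.frame"))
  expect_equal(second_harmonic_intensity(tr, 0),
               tr$C2 * sin(tr$phi))
  expect_equal(second_harmonic_intensity(tr, pi / 2)[1], 0.01)
  # phi_eff = 0 kills the intensity regardless of C2
  tr0 <- tr; tr0$phi <- -0.4
  expect_equal(second_harmonic_intensity(tr0, 0.4), rep(0, 5),
               tolerance = 1e-12)
})

test_that("the steering correlation behaves like a non-centred cosine", {
  mk_trace <- function(C2, phi) {
    structure(data.frame(t = seq_along(C2) * 0.06, f0 = 20, C1 = 0.1,
                         C2 = C2, phi = phi),
              class = c("harmonic_trace", "data.frame"))
  }
  set.seed(42)
  n <- 1000
  C2 <- abs(stats::rnorm(n, 0.015, 0.004))
  phi <- stats::runif(n, -1, 1.5)
  tr <- mk_trace(C2, phi)
  I <- C2 * sin(phi + 0.3)
  rot <- data.frame(t = tr$t, Omega = 20 * 0.7 * I)   # proportional
  expect_equal(correlation_R(rot, tr, 0.3), 1, tolerance = 1e-9)
  # invariant under positive rescaling of either series
  rot2 <- rot; rot2$Omega <- 3.7 * rot$Omega
  expect_equal(correlation_R(rot2, tr, 0.3), 1, tolerance = 1e-9)
  # independent white series: |R| < 0.1 for 95% of seeds
  Rs <- vapply(1:40, function(sd) {
    set.seed(sd)
    trn <- mk_trace(abs(stats::rnorm(n, 0.015, 0.004)),
                    stats::runif(n, -pi, pi))
    rotn <- data.frame(t = trn$t, Omega = stats::rnorm(n, 0, 0.1))
    correlation_R(rotn, trn, 0)
  }, numeric(1))
  expect_lte(stats::quantile(abs(Rs), 0.95, names = FALSE), 0.1)
  # identically zero series are refused
  rot0 <- rot; rot0$Omega <- 0
  expect_error(correlation_R(rot0, tr, 0), "zero")
})

test_that("the optimal phase offset is recovered and flagged when flat", {
  set.seed(7)
  n <- 400
  C2 <- abs(stats::rnorm(n, 0.015, 0.004))
  phi <- flagbeat:::gaussian_smooth(stats::rnorm(n, 0, 1.2), 0.06, 0.5)
  tr <- structure(data.frame(t = seq_len(n) * 0.06, f0 = 20, C1 = 0.1,
                             C2 = C2, phi = phi),
                  class = c("harmonic_trace", "data.frame"))
  I <- C2 * sin(phi + 0.7)
  rot <- data.frame(t = tr$t, Omega = 20 * I * (1 + 0.1 * stats::rnorm(n)))
  opt <- optimize_phase_offset(rot, tr)
  expect_true(opt$identifiable)
  expect_lt(abs(flagbeat:::wrap_angle(opt$phi0 - 0.7)), 0.05)
  expect_gt(opt$R_max, 0.9)
  # closed-form argmax for constant C2 and a phase ramp: the ramp makes
  # <sin^2(phi + p0)> independent of p0, so maximising the numerator
  # quadratures a cos(p0) + b sin(p0) is exact
  phi_r <- seq(0, 12 * pi, length.out = n)
  tr2 <- tr; tr2$C2 <- 0.015; tr2$phi <- phi_r
  rot2 <- data.frame(t = tr$t, Omega = sin(phi_r + 0.7))
  opt2 <- optimize_phase_offset(rot2, tr2)
  a <- mean(rot2$Omega / 20 * 0.015 * sin(phi_r))
  b <- mean(rot2$Omega / 20 * 0.015 * cos(phi_r))
  expect_lt(abs(flagbeat:::wrap_angle(opt2$phi0 - atan2(b, a))), 0.05)
  expect_lt(abs(flagbeat:::wrap_angle(opt2$phi0 - 0.7)), 0.05)
  # uncorrelated rotation: flat objective is flagged
  set.seed(8)
  rot3 <- data.frame(t = tr$t, Omega = stats::rnorm(n, 0, 1e-4))
  res <- suppressWarnings(optimize_phase_offset(rot3, tr))
  expect_lt(res$R_max, 0.3)
})

test_that("the correlation is probe-independent for a shared-wavenumber wave", {
  set.seed(3)
  t <- seq(0, 20, by = 1 / 500)
  dr <- random_drift(t, C2_mean = 0.015, C2_sd = 0.005, phi_mean = 0.8,
                     phi_sd = 0.6, noise_sd = 0.005, seed = 11)
  spec <- ref_spec(C2 = 0.015, phi = 0.8)
  drag <- drag_model()
  K <- spec$omega0 * (3 * spec$L^3 / (4 * (2 * pi)^4)) *
    ((drag$xi_perp - drag$xi_par) / drag$xi_perp) / (2 * pi)
  I_true <- dr$C2_fun(t) * sin(dr$phi_fun(t) + 0.7)
  om_fun <- stats::approxfun(t, K * spec$C1^2 * I_true *
                               (1 + 0.1 * stats::rnorm(length(t))), rule = 2)
  tracks <- gen_rotating_cell(spec, dr, omega_fun = om_fun,
                              s = seq(0, 36, by = 0.9), t = t,
                              skip_points = 3, seed = 4)
  cf <- curvature_three_point(tracks)
  rot <- rotation_velocity(tracks)
  tab <- probe_consistency(cf, rot, s_list = c(15, 25), s_ref = 25)
  expect_lt(abs(tab$R[tab$s0 == 15] - tab$R[tab$s0 == 25]), 0.05)
  expect_gt(min(tab$R), 0.85)
  # single probe gives a one-row table
  tab1 <- probe_consistency(cf, rot, s_list = 25)
  expect_equal(nrow(tab1), 1L)
})
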