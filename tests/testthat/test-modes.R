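# Principal beat modes, significance null, limit-cycle phase, alignment.

test_that("a traveling wave yields a degenerate sin/cos mode pair", {
  # window of exactly one wavelength: sin(ks) and cos(ks) carry equal
  # weight, so the eigenvalue pair is degenerate
  s <- seq(0, 40, by = 0.8)
  t <- seq(0, 2, by = 1 / 500)
  k <- 2 * pi / 40
  C <- 0.08 * outer(s, t, function(s, t) cos(k * s - 2 * pi * 20 * t))
  md <- covariance_modes(curvature_field(C, s, t))
  expect_equal(md$sigma[1] / md$sigma[2], 1, tolerance = 0.01)
  expect_lt(md$sigma[3] / md$sigma[1], 1e-10)
  # the leading pair spans sin(ks), cos(ks): project the basis onto it
  basis <- cbind(sin(k * s), cos(k * s))
  proj <- lm.fit(md$Gamma[, 1:2], basis)
  expect_lt(max(abs(proj$residuals)), 1e-6)
})

test_that("mode decomposition is exact, orthonormal and conserves variance", {
  cf <- ref_field(noise_sd = 0.005)
  md <- covariance_modes(cf)
  # quadrature orthonormality
  G <- t(md$Gamma) %*% (md$Gamma * md$w)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  # completeness
  rec <- reconstruct(md, length(md$sigma))
  expect_lt(max(abs(rec$C - cf$C)) / max(abs(cf$C)), 1e-8)
  # energy bookkeeping: sum of eigenvalues = quadrature-weighted mean square
  total <- mean(colSums(cf$C^2 * md$w))
  expect_equal(sum(md$sigma), total, tolerance = 1e-6)
  # truncation residual equals the dropped eigenvalues
  rec2 <- reconstruct(md, 2)
  resid <- mean(colSums((cf$C - rec2$C)^2 * md$w))
  expect_equal(resid, sum(md$sigma[-(1:2)]), tolerance = 0.01)
  expect_error(covariance_modes(curvature_field(matrix(NaN, 2, 5), 1:2,
                                                (1:5) / 500)), "NaN")
})

test_that("two harmonics concentrate at least 90% of variance in two modes", {
  cf <- ref_field(ref_spec(C2 = 0.03, phi = 0.5), noise_sd = 0.005)
  md <- covariance_modes(cf)
  expect_gte(sum(md$var_frac[1:2]), 0.9)
  # and a 3-mode reconstruction captures ~95%+ at this noise level
  expect_gte(sum(md$var_frac[1:3]), 0.95)
})

test_that("significance counting: 0 for noise, 2 for two harmonics, 3 with offset drift", {
  s <- seq(0, 36, by = 0.9)
  t <- seq(0, 4, by = 1 / 500)
  noise <- gen_random_curvature(0.05, s, t, seed = 3)
  expect_equal(as.integer(significant_modes(covariance_modes(noise), noise,
                                            replicates = 30, seed = 11)), 0L)
  cf <- gen_curvature_wave(ref_spec(), drift_profile(noise_sd = 0.005),
                           s = s, t = t, seed = 5)
  expect_equal(as.integer(significant_modes(covariance_modes(cf), cf,
                                            replicates = 30, seed = 11)), 2L)
  dr <- random_drift(t, C2_mean = 0.03, C2_sd = 0.005, phi_mean = 0.5,
                     phi_sd = 0.3, C0_mean = 0, C0_sd = 0.02,
                     noise_sd = 0.005, seed = 4)
  cf3 <- gen_curvature_wave(ref_spec(), dr, s = s, t = t, seed = 6)
  expect_equal(as.integer(significant_modes(covariance_modes(cf3), cf3,
                                            replicates = 30, seed = 11)), 3L)
})

test_that("beat phase traces the limit cycle at the beat frequency", {
  cf <- ref_field(seconds = 4)
  md <- covariance_modes(cf)
  bp <- beat_phase(md)
  ok <- !is.na(bp$alpha)
  # mean phase velocity over whole cycles = fundamental frequency within 1%
  f_mean <- abs(bp$alpha[max(which(ok))] - bp$alpha[min(which(ok))]) /
    (bp$t[max(which(ok))] - bp$t[min(which(ok))]) / (2 * pi)
  expect_equal(f_mean, 20, tolerance = 0.01)
  # normalised histogram integrates to 1
  expect_equal(sum(bp$P) * diff(bp$chi1_breaks)[1] * diff(bp$chi2_breaks)[1],
               1, tolerance = 1e-9)
  # single-frequency cycle on a one-wavelength window: isotropic ring
  cf1 <- gen_curvature_wave(ref_spec(C2 = 0), s = seq(0, 40, by = 0.8),
                            t = seq(0, 4, by = 1 / 500))
  bp1 <- beat_phase(covariance_modes(cf1))
  amp <- sqrt(bp1$chi1^2 + bp1$chi2^2)
  expect_lt(stats::sd(amp) / mean(amp), 0.01)
  # degenerate: a standing wave with chi2 ~ 0 is flagged
  s <- cf$s; t <- cf$t
  stand <- curvature_field(0.1 * outer(sin(2 * pi * s / 40),
                                       cos(2 * pi * 20 * t)), s, t)
  expect_warning(beat_phase(covariance_modes(stand)), "degenerate")
})

test_that("conditional frequency is flat for one harmonic, bimodal for two", {
  # the sense of the (chi1, chi2) cycle depends on the arbitrary relative
  # sign of the eigenvector pair; orient each result positively
  orient <- function(om) {
    s <- sign(mean(om$omega_hz, na.rm = TRUE))
    om$omega_hz <- s * om$omega_hz
    om
  }
  # one-wavelength windows keep the (chi1, chi2) cycle isotropic; on a
  # truncated window the ellipticity of the cycle adds a spurious
  # once-per-cycle modulation of the phase velocity
  s1 <- seq(0, 40, by = 0.8)
  cf1 <- gen_curvature_wave(ref_spec(C2 = 0), s = s1,
                            t = seq(0, 4, by = 1 / 500))
  om1 <- orient(conditional_frequency(beat_phase(covariance_modes(cf1))))
  expect_lt(diff(range(om1$omega_hz, na.rm = TRUE)), 0.02 * 20)
  expect_equal(mean(om1$omega_hz, na.rm = TRUE), 20, tolerance = 0.02)
  # two harmonics: the phase velocity oscillates twice per cycle
  # two harmonics: both ride on the same leading mode pair (shared
  # wavenumber), so the cycle is z = C1 e^{-iwt} (1 + r e^{-i(wt-phi)}),
  # r = C2/C1, whose phase velocity is modulated once per cycle between
  # w (1-2r)/(1-r) and w (1+2r)/(1+r): extreme ratio
  # (1+2r)(1-r) / ((1-2r)(1+r)), reaching the 20/40 Hz (1:2) extremes at
  # r = (sqrt(17)-3)/4 ~ 0.28
  ratio_of <- function(r) (1 + 2 * r) * (1 - r) / ((1 - 2 * r) * (1 + r))
  for (r in c(1 / 6, (sqrt(17) - 3) / 4)) {
    cfr2 <- gen_curvature_wave(ref_spec(C2 = 0.1 * r, phi = 0.5), s = s1,
                               t = seq(0, 4, by = 1 / 500))
    omr2 <- orient(conditional_frequency(beat_phase(covariance_modes(cfr2)),
                                         n_bins = 18))
    expect_true(all(is.finite(omr2$omega_hz)))
    expect_equal(max(omr2$omega_hz) / min(omr2$omega_hz), ratio_of(r),
                 tolerance = 0.12)
    # modulated once per cycle: exactly one maximum and one minimum around
    # the circular profile
    d <- diff(c(omr2$omega_hz, omr2$omega_hz[1]))
    expect_equal(sum(diff(sign(d[d != 0])) != 0) +
                   (sign(d[d != 0][1]) != sign(d[d != 0][sum(d != 0)])),
                 2)
  }
  # time reversal negates the profile.  A degenerate mode pair leaves the
  # in-plane orientation (including reflections) arbitrary, so this needs a
  # fixture with split eigenvalues: the truncated 36 um window
  cf2 <- ref_field(ref_spec(C2 = 0.03, phi = 0.5), seconds = 4)
  cfr <- cf2
  cfr$C <- cf2$C[, rev(seq_len(ncol(cf2$C)))]
  o1 <- conditional_frequency(beat_phase(covariance_modes(cf2)), n_bins = 18)
  o2 <- conditional_frequency(beat_phase(covariance_modes(cfr)), n_bins = 18)
  ok <- is.finite(o1$omega_hz) & is.finite(o2$omega_hz)
  expect_gt(sum(ok), 10)
  expect_equal(o2$omega_hz[ok], -o1$omega_hz[ok], tolerance = 0.02)
})

test_that("mode alignment recovers identity, signed permutations and collapse", {
  cf <- ref_field()
  md <- covariance_modes(cf)
  self <- align_modes(md, md, lambda = 40)
  expect_equal(self$overlap, 1, tolerance = 1e-6)
  expect_equal(abs(self$transform), diag(2), tolerance = 1e-3)
  # swapped and negated modes: recovered transform is the signed permutation
  md2 <- md
  md2$Gamma <- md$Gamma[, c(2, 1, 3:ncol(md$Gamma))]
  md2$Gamma[, 1] <- -md2$Gamma[, 1]
  al <- align_modes(md2, md, lambda = 40)
  expect_equal(al$overlap, 1, tolerance = 1e-6)
  expect_equal(abs(al$transform), matrix(c(0, 1, 1, 0), 2), tolerance = 1e-3)
  # two cells with the same normalised waveform but different wavelengths
  mk <- function(lambda) {
    spec <- waveform_spec(C1 = 0.1, C2 = 0.02, f0 = 20, lambda = lambda,
                          phi = 0.4, L = 0.9 * lambda)
    covariance_modes(gen_curvature_wave(
      spec, s = seq(0, spec$L, by = 0.9), t = seq(0, 2, by = 1 / 500)))
  }
  ma <- mk(35); mb <- mk(50)
  al2 <- align_modes(ma, mb, lambda = 35, lambda_ref = 50)
  ref <- cbind(stats::approx(mb$s / 50, mb$Gamma[, 1], xout = al2$s_scaled)$y,
               stats::approx(mb$s / 50, mb$Gamma[, 2], xout = al2$s_scaled)$y)
  ref <- sweep(ref, 2, sqrt(colSums(ref^2)), `/`)
  gap <- max(abs(al2$Gamma - ref)) / max(abs(ref))
  expect_lt(gap, 0.05)
  # incompatible reference warns
  junk <- md
  junk$Gamma[, 1:2] <- matrix(stats::rnorm(2 * nrow(md$Gamma), sd = 1),
                              ncol = 2)
  expect_warning(try(align_modes(md, junk, lambda = 40), silent = TRUE))
})
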