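# Principal-component decomposition of the curvature field, significance
# against a random-curvature null, limit-cycle phase, and cross-cell mode
# alignment.
#
# The normal modes Gamma_n(s) are eigenvectors of the non-standardised
# arclength covariance M(s, s') = <C(s,t) C(s',t)>_t (no mean removal: the
# time-average curvature is approximately zero).  Orthonormality is taken
# with respect to trapezoid quadrature on the arclength grid, so that the
# amplitudes chi_n(t) = int C Gamma_n ds reconstruct the field exactly when
# all modes are kept.

#' Principal beat modes of a curvature field
#'
#' Eigen-decomposition of the arclength covariance of `C(s,t)` without
#' standardisation or mean removal.  Modes are orthonormal under the
#' trapezoid quadrature inner product on the `s` grid and sorted by
#' decreasing eigenvalue; amplitudes are the quadrature projections of each
#' frame onto the modes.
#'
#' @param field a [curvature_field]; must be NaN-free and have more time
#'   samples than arclength samples.
#' @return an object of class `mode_decomposition`: list with `Gamma`
#'   (s x n modes), `sigma` (eigenvalues, curvature^2 um units), `chi`
#'   (time x n amplitudes), `var_frac`, `s`, `t`, `w` (quadrature weights).
#' @export
covariance_modes <- function(field) {
  if (any(!is.finite(field$C))) stop("NaN in curvature field")
  ns <- nrow(field$C); nt <- ncol(field$C)
  if (nt <= ns) stop("need more time samples than arclength samples")
  w <- trapz_weights(field$s)
  M <- field$C %*% t(field$C) / nt             # <C(s) C(s')>_t
  sw <- sqrt(w)
  B <- M * outer(sw, sw)                       # symmetrised weighted form
  eg <- eigen(B, symmetric = TRUE)
  sigma <- pmax(eg$values, 0)
  Gamma <- eg$vectors / sw                     # quadrature-orthonormal modes
  # canonical sign: the extremal element of each mode is positive (the sign
  # of an eigenvector is arbitrary; fixing it makes runs reproducible)
  flip <- vapply(seq_len(ncol(Gamma)), function(j) {
    sign(Gamma[which.max(abs(Gamma[, j])), j])
  }, numeric(1))
  Gamma <- sweep(Gamma, 2, flip, `*`)
  chi <- t(field$C * w) %*% Gamma              # chi_n(t) = int C Gamma_n ds
  structure(list(
    Gamma = Gamma, sigma = sigma, chi = chi,
    var_frac = sigma / sum(sigma),
    s = field$s, t = field$t, w = w
  ), class = "mode_decomposition")
}

#' @export
print.mode_decomposition <- function(x, ...) {
  cat(sprintf("Mode decomposition: %d modes over %d arclength points\n",
              length(x$sigma), length(x$s)))
  n <- min(5, length(x$sigma))
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", x$var_frac[1:n]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.mode_decomposition <- function(x, n = 2, ...) {
  graphics::matplot(x$s, x$Gamma[, seq_len(n), drop = FALSE], type = "l",
                    lty = 1, xlab = "arclength (um)", ylab = "mode amplitude",
                    ...)
  invisible(x)
}

#' Number of significant modes against a random-curvature null
#'
#' Compares the observed eigenvalue spectrum with spectra of delta-correlated
#' Gaussian curvature fields whose per-entry variance equals the variance of
#' the original curvature.  A mode is significant when its eigenvalue exceeds
#' the 95th percentile of the null eigenvalues at the same rank; the count is
#' the length of the leading run of significant ranks.
#'
#' @param decomp a `mode_decomposition`.
#' @param field the [curvature_field] that produced it (sets the null
#'   variance and grid).
#' @param replicates number of null fields (>= 20).
#' @param seed RNG seed.
#' @param quantile_level per-rank null quantile.
#' @return integer count of significant modes, with the per-rank null
#'   thresholds in `attr(, "null_q")`.
#' @export
significant_modes <- function(decomp, field, replicates = 50, seed = 1,
                              quantile_level = 0.95) {
  stopifnot(replicates >= 20)
  sigma_noise <- stats::sd(as.vector(field$C))
  nulls <- vapply(seq_len(replicates), function(r) {
    cf <- gen_random_curvature(sigma_noise, field$s, field$t,
                               seed = seed + r)
    covariance_modes(cf)$sigma
  }, numeric(length(decomp$sigma)))
  null_q <- apply(nulls, 1, stats::quantile, probs = quantile_level)
  sig <- decomp$sigma > null_q
  n_sig <- if (sig[1]) which.min(c(sig, FALSE)) - 1L else 0L
  structure(n_sig, null_q = null_q)
}

#' Reconstruct a curvature field from leading modes
#'
#' `C_rec(s,t) = sum_{i=1}^{n} Gamma_i(s) chi_i(t)`.  With all modes the
#' reconstruction is exact; the residual variance of a truncated
#' reconstruction equals the sum of the dropped eigenvalues.
#'
#' @param decomp a `mode_decomposition`.
#' @param n_modes number of leading modes to keep.
#' @return a [curvature_field].
#' @export
reconstruct <- function(decomp, n_modes) {
  stopifnot(n_modes >= 1, n_modes <= length(decomp$sigma))
  idx <- seq_len(n_modes)
  C <- decomp$Gamma[, idx, drop = FALSE] %*% t(decomp$chi[, idx, drop = FALSE])
  curvature_field(C, decomp$s, decomp$t)
}

#' Beat phase from the two leading mode amplitudes
#'
#' The beat phase is `alpha(t) = atan2(chi_2, chi_1)`, unwrapped; over one
#' beat cycle it advances by 2*pi.  The joint density P(chi1, chi2) is
#' returned as a normalised 2D histogram; for a single-frequency beat it is
#' an isotropic ring, and a second harmonic concentrates probability in two
#' opposite regions of the cycle.
#'
#' @param decomp a `mode_decomposition` (first two modes are used).
#' @param n_bins histogram bins per axis.
#' @param amp_floor_frac samples with `chi1^2 + chi2^2` below
#'   `(amp_floor_frac * rms amplitude)^2` are masked.
#' @return object of class `beat_phase`: list with `t`, `alpha` (unwrapped,
#'   rad; masked samples NA), `chi1`, `chi2`, `P` (normalised histogram),
#'   `chi1_breaks`, `chi2_breaks`, `masked`, `degenerate` (TRUE when one
#'   amplitude is identically ~0).
#' @export
beat_phase <- function(decomp, n_bins = 50, amp_floor_frac = 0.05) {
  chi1 <- decomp$chi[, 1]; chi2 <- decomp$chi[, 2]
  amp2 <- chi1^2 + chi2^2
  floor2 <- (amp_floor_frac^2) * mean(amp2)
  masked <- amp2 < floor2
  alpha_raw <- atan2(chi2, chi1)
  alpha <- unwrap_angle(alpha_raw)
  alpha[masked] <- NA
  degenerate <- stats::sd(chi2) < 1e-10 * max(stats::sd(chi1), 1e-300) ||
    stats::sd(chi1) < 1e-10 * max(stats::sd(chi2), 1e-300)
  if (degenerate) {
    warning("one mode amplitude is degenerate; the beat phase collapses to {0, pi}")
  }
  b1 <- seq(min(chi1), max(chi1), length.out = n_bins + 1)
  b2 <- seq(min(chi2), max(chi2), length.out = n_bins + 1)
  h <- table(cut(chi1, b1, include.lowest = TRUE),
             cut(chi2, b2, include.lowest = TRUE))
  P <- unclass(h) / (length(chi1) * diff(b1)[1] * diff(b2)[1])
  structure(list(t = decomp$t, alpha = alpha, chi1 = chi1, chi2 = chi2,
                 P = P, chi1_breaks = b1, chi2_breaks = b2,
                 masked = masked, degenerate = degenerate),
            class = "beat_phase")
}

#' Conditional beat frequency around the limit cycle
#'
#' The phase velocity `d alpha/dt`, binned by the phase `alpha` modulo 2*pi:
#' `omega(alpha) = <d alpha/dt | alpha>`, reported in Hz.  For a pure
#' single-frequency cycle this is flat at the beat frequency; a second
#' harmonic makes the frequency oscillate twice per cycle.
#'
#' @param phase a `beat_phase`.
#' @param n_bins number of phase bins.
#' @param min_count bins with fewer samples are masked.
#' @return data.frame with `alpha` (bin centre, rad in [0, 2*pi)),
#'   `omega_hz` (mean), `sd_hz`, `n`.
#' @export
conditional_frequency <- function(phase, n_bins = 36, min_count = 20) {
  ok <- !is.na(phase$alpha)
  t <- phase$t[ok]; alpha <- phase$alpha[ok]
  if (length(t) < 3) stop("too few unmasked samples")
  dt <- stats::median(diff(t))
  n_cycles <- abs(alpha[length(alpha)] - alpha[1]) / (2 * pi)
  if (n_cycles < 10) stop("need at least 10 beat cycles")
  dadt <- central_diff(alpha, dt) / (2 * pi)     # Hz
  a_mod <- alpha %% (2 * pi)
  bins <- floor(a_mod / (2 * pi) * n_bins) + 1
  agg_m <- tapply(dadt, bins, mean)
  agg_s <- tapply(dadt, bins, stats::sd)
  agg_n <- tapply(dadt, bins, length)
  out <- data.frame(alpha = (seq_len(n_bins) - 0.5) * 2 * pi / n_bins,
                    omega_hz = NA_real_, sd_hz = NA_real_, n = 0L)
  idx <- as.integer(names(agg_m))
  out$omega_hz[idx] <- agg_m
  out$sd_hz[idx] <- agg_s
  out$n[idx] <- agg_n
  out$omega_hz[out$n < min_count] <- NA
  out$sd_hz[out$n < min_count] <- NA
  out
}

#' Align a pair of beat modes to a reference pair
#'
#' Rescales arclength to wavelength units (`s -> s/lambda`), interpolates
#' both mode pairs onto the overlapping scaled grid, and finds the 2x2
#' orthogonal transform (rotation, optionally with reflection) that
#' maximises the overlap with the reference pair: a 1-degree grid search
#' over O(2) followed by a closed-form orthogonal Procrustes polish.
#' Different cells beating with the same normalised waveform collapse onto
#' common mode curves after this alignment.
#'
#' @param decomp a `mode_decomposition` (first two modes used).
#' @param reference a `mode_decomposition` or a list with `Gamma` and `s`.
#' @param lambda,lambda_ref beat wavelengths (um) of `decomp` and the
#'   reference.
#' @return list with `Gamma` (aligned modes on the scaled grid), `s_scaled`,
#'   `transform` (2x2), `overlap` (mean cosine similarity in [0, 1]); warns
#'   when the overlap stays below 0.5.
#' @export
align_modes <- function(decomp, reference, lambda, lambda_ref = lambda) {
  u <- decomp$s / lambda
  v <- reference$s / lambda_ref
  lo <- max(min(u), min(v)); hi <- min(max(u), max(v))
  grid <- seq(lo, hi, length.out = 200)
  interp2 <- function(s, G) {
    cbind(stats::approx(s, G[, 1], xout = grid)$y,
          stats::approx(s, G[, 2], xout = grid)$y)
  }
  A <- interp2(u, decomp$Gamma[, 1:2])          # to be transformed
  Rf <- interp2(v, reference$Gamma[, 1:2])      # target
  normalise <- function(M) sweep(M, 2, sqrt(colSums(M^2)), `/`)
  A <- normalise(A); Rf <- normalise(Rf)
  score <- function(Q) {
    T1 <- A %*% Q
    mean(abs(colSums(T1 * Rf)) / sqrt(colSums(T1^2)))
  }
  best <- list(score = -Inf, Q = diag(2))
  for (refl in c(1, -1)) {
    for (deg in seq(0, 359, by = 1)) {
      th <- deg * pi / 180
      Q <- rot2(th) %*% diag(c(1, refl))
      sc <- score(Q)
      if (sc > best$score) best <- list(score = sc, Q = Q)
    }
  }
  # Procrustes polish: orthogonal Q maximising tr(Q^T A^T Rf)
  sv <- svd(t(A) %*% Rf)
  Qp <- sv$u %*% t(sv$v)
  if (score(Qp) > best$score) best <- list(score = score(Qp), Q = Qp)
  if (best$score < 0.5) warning("modes incompatible: overlap below 0.5")
  list(Gamma = A %*% best$Q, s_scaled = grid, transform = best$Q,
       overlap = best$score)
}
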