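# Resistive-force-theory closed forms for the rotation of a tethered cell,
# and a numerical quadrature oracle that evaluates the same quantity from
# the exact beating shape.
#
# Conventions: curvature positive for counter-clockwise bends; rotation
# velocity Omega reported in revolutions per second, positive counter-
# clockwise; drag coefficients per unit length in fN s / um^2.

#' Anisotropic drag model
#'
#' Perpendicular and tangential drag coefficients per unit length of a
#' slender filament.  The anisotropy `xi_perp/xi_par > 1` is what converts
#' lateral beating into propulsion and torque.
#'
#' @param xi_par tangential drag coefficient (fN s / um^2).
#' @param ratio anisotropy `xi_perp / xi_par`; must exceed 1 for a slender
#'   filament.
#' @param xi_perp perpendicular drag coefficient; overrides `ratio` when
#'   given.
#' @return object of class `drag_model` with `xi_perp`, `xi_par`, `ratio`.
#' @export
#' @examples
#' drag_model()  # xi_par = 0.69 fN s/um^2, ratio 1.81
drag_model <- function(xi_par = 0.69, ratio = 1.81, xi_perp = NULL) {
  if (is.null(xi_perp)) xi_perp <- ratio * xi_par
  stopifnot(xi_par > 0, xi_perp > 0)
  structure(list(xi_perp = xi_perp, xi_par = xi_par,
                 ratio = xi_perp / xi_par), class = "drag_model")
}

#' Cycle-averaged net transverse force density (small-amplitude form)
#'
#' For the small-amplitude waveform
#' `y(x,t) = y1 sin(kx - w0 t) + y2 sin(kx - 2 w0 t + phi)`, the transverse
#' force per unit length that the filament exerts on the fluid, averaged
#' over one beat cycle, is
#' `f_y(x) = w0 k^2 (xi_perp - xi_par) y1^2 y2 cos(kx - phi)`.
#' It vanishes without a second harmonic or without drag anisotropy.  The
#' cycle-averaged drag force acting back on the filament is its negative.
#'
#' @param spec a [waveform_spec()]; its `y1`, `y2` displacement amplitudes
#'   (um) are used.
#' @param drag a [drag_model()].
#' @param x positions along the average axis (um).
#' @return force density at `x` (fN / um).
#' @export
net_transverse_force <- function(spec, drag, x) {
  spec$omega0 * spec$k^2 * (drag$xi_perp - drag$xi_par) *
    spec$y1^2 * spec$y2 * cos(spec$k * x - spec$phi)
}

#' Rotation velocity from the second harmonic (closed form)
#'
#' The lambda -> L limit of the small-curvature resistive-force-theory
#' result for a tethered cell:
#' `Omega = -w0 * (3 L^3 / (4 (2 pi)^4)) * ((xi_perp - xi_par)/xi_perp) *
#'  C1^2 C2 sin(phi)`,
#' converted to revolutions per second.  Rotation requires both a second
#' harmonic (C2 > 0) and a phase with `sin(phi) != 0`; with the counter-
#' clockwise-positive curvature convention, positive `C2 sin(phi)` drives
#' clockwise rotation.
#'
#' @param spec a [waveform_spec()] (curvature form).
#' @param drag a [drag_model()].
#' @param L flagellar length (um); defaults to `spec$L`.
#' @return Omega (rev/s, signed).  Warns when `lambda/L` is outside
#'   `[0.8, 1.25]`, the neighbourhood of the wavelength-matched limit.
#' @export
omega_second_harmonic <- function(spec, drag, L = spec$L) {
  rl <- spec$lambda / L
  if (rl < 0.8 || rl > 1.25) {
    warning("lambda/L = ", signif(rl, 3),
            " outside the validity window of the lambda -> L closed form")
  }
  omega_rad <- -spec$omega0 * (3 * L^3 / (4 * (2 * pi)^4)) *
    ((drag$xi_perp - drag$xi_par) / drag$xi_perp) *
    spec$C1^2 * spec$C2 * sin(spec$phi)
  omega_rad / (2 * pi)
}

#' Rotation velocity from intrinsic curvature (closed form)
#'
#' Small-curvature result for a static curvature offset C0:
#' `Omega = w0 * (L^3 / (2 pi)^6) * ((xi_perp - xi_par)/xi_perp) *
#'  C1^2 C0 * pi (pi^2 - 3)`,
#' in revolutions per second.  Comparing coefficients with
#' [omega_second_harmonic()], equal magnitudes of C0 and C2 contribute to
#' rotation at the same order.
#'
#' @param C0 intrinsic (static) curvature (1/um).
#' @param C1 fundamental curvature amplitude (1/um).
#' @param drag a [drag_model()].
#' @param L flagellar length (um).
#' @param omega0 fundamental angular frequency (rad/s).
#' @return Omega (rev/s, signed; linear in C0).
#' @export
omega_intrinsic_curvature <- function(C0, C1, drag, L, omega0 = 2 * pi * 20) {
  omega_rad <- omega0 * (L^3 / (2 * pi)^6) *
    ((drag$xi_perp - drag$xi_par) / drag$xi_perp) *
    C1^2 * C0 * pi * (pi^2 - 3)
  omega_rad / (2 * pi)
}

#' Numerical rotation oracle by resistive-force-theory quadrature
#'
#' Independent numerical evaluation of the tethered-cell rotation velocity:
#' the exact (not small-amplitude) shape sequence is built from the
#' curvature wave by tangent-angle integration in the zero-mean-tangent body
#' frame with the base pinned at the pivot; resistive-force-theory drag
#' force densities follow from the material velocities; the torque about the
#' pivot is time-averaged over an integer number of fundamental periods and
#' divided by the rotational drag of the time-averaged (straight) shape,
#' `xi_perp L^3 / 3`.
#'
#' The body-frame gauge matters at the rectified (cubic) order; the
#' zero-mean-tangent frame is used because it is parity-correct (a pure
#' fundamental gives |Omega| at machine precision) and represents the mean
#' orientation of the cell.  Unlike the leading-order closed forms, the
#' exact construction keeps the geometric-phase contribution of the cyclic
#' shape change, so a small rotation survives even with isotropic drag.
#' See the methods vignette for the comparison with the closed form.
#'
#' @param spec a [waveform_spec()] (curvature form, C0 included).
#' @param drag a [drag_model()].
#' @param L flagellar length (um); defaults to `spec$L`.
#' @param n_periods number of fundamental periods (integer >= 1).
#' @param ns,nt arclength and time resolution (>= 200 per length and
#'   period).
#' @return Omega (rev/s, signed).
#' @export
kinematic_omega_oracle <- function(spec, drag, L = spec$L, n_periods = 1,
                                   ns = 1000, nt = 2000) {
  if (n_periods != round(n_periods)) {
    stop("n_periods must cover an integer number of fundamental periods")
  }
  stopifnot(ns >= 200, nt >= 200)
  k <- spec$k; w <- spec$omega0
  s <- seq(0, L, length.out = ns); ds <- s[2] - s[1]
  Tper <- 2 * pi / w * n_periods
  tt <- seq(0, Tper, length.out = nt + 1)[1:nt]   # periodic grid
  dt <- Tper / nt
  C <- spec$C0 + outer(s, tt, function(s, t) {
    spec$C1 * sin(k * s - w * t) + spec$C2 * sin(k * s - 2 * w * t + spec$phi)
  })
  th <- apply(C, 2, function(cc) cumtrapz(s, cc))
  th <- sweep(th, 2, colMeans(th))                # zero-mean-tangent gauge
  cx <- cos(th); sx <- sin(th)
  X <- apply(cx, 2, function(v) cumtrapz(s, v))   # base pinned at origin
  Y <- apply(sx, 2, function(v) cumtrapz(s, v))
  ip <- c(2:nt, 1); im <- c(nt, 1:(nt - 1))       # periodic central diff
  VX <- (X[, ip] - X[, im]) / (2 * dt)
  VY <- (Y[, ip] - Y[, im]) / (2 * dt)
  vt <- VX * cx + VY * sx
  vn <- -VX * sx + VY * cx
  fX <- -(drag$xi_par * vt * cx - drag$xi_perp * vn * sx)
  fY <- -(drag$xi_par * vt * sx + drag$xi_perp * vn * cx)
  tau <- X * fY - Y * fX
  T0 <- colSums((tau[-1, , drop = FALSE] + tau[-ns, , drop = FALSE]) / 2) * ds
  mean(T0) / (drag$xi_perp * L^3 / 3) / (2 * pi)
}
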