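# Shape integration: from a curvature field to tracked point coordinates,
# optionally with rigid-body rotation about the tethering point.

#' Integrate a curvature field into tracked points
#'
#' Reconstructs midline coordinates from curvature by tangent-angle
#' integration, `theta(s) = theta0 + int C ds'`, followed by quadrature of
#' the unit tangent.  This is the inverse of [curvature_three_point()] up to
#' discretisation error O(ds^2).
#'
#' @param field a [curvature_field]; values must be finite.
#' @param pivot base position (um), the first point of every frame.
#' @param theta0 base tangent angle (rad), either a scalar or one value per
#'   frame.
#' @return a [flagellum_tracks] with one point per arclength node.
#' @export
#' @examples
#' cf <- curvature_field(matrix(0.1, 40, 3), s = seq(0, 39) * 1, t = 0:2 / 500)
#' tr <- integrate_shape(cf)  # circular arc, radius 10 um
integrate_shape <- function(field, pivot = c(0, 0), theta0 = 0) {
  if (any(!is.finite(field$C))) stop("NaN or infinite curvature")
  ds_max <- max(diff(field$s))
  if (max(abs(field$C)) * ds_max >= pi / 2) {
    stop("curvature step |C| * ds exceeds pi/2; refine the arclength grid")
  }
  nt <- ncol(field$C)
  np <- nrow(field$C)
  theta0 <- rep_len(theta0, nt)
  # theta on the s grid per frame, then positions by trapezoid quadrature
  th <- apply(field$C, 2, function(cc) cumtrapz(field$s, cc))
  th <- sweep(th, 2, theta0, `+`)
  cx <- cos(th); sx <- sin(th)
  X <- pivot[1] + apply(cx, 2, function(v) cumtrapz(field$s, v))
  Y <- pivot[2] + apply(sx, 2, function(v) cumtrapz(field$s, v))
  flagellum_tracks(
    frame = rep(seq_len(nt), each = np),
    time_s = rep(field$t, each = np),
    point_index = rep(seq_len(np), nt),
    x_um = as.vector(X), y_um = as.vector(Y),
    pivot = pivot
  )
}

#' Synthetic tethered cell with prescribed rotation
#'
#' Generates a beating flagellum (via [gen_curvature_wave()] and
#' [integrate_shape()]) whose whole frame additionally rotates rigidly about
#' the tethering point by the angle `2*pi*int Omega dt`, emulating a tethered
#' cell revolving at rotation velocity `Omega(t)` (rev/s, positive
#' counter-clockwise).
#'
#' @param spec a [waveform_spec()].
#' @param drift a [drift_profile()] or `NULL`.
#' @param omega_fun function of time returning Omega(t) in rev/s, or a single
#'   number for constant rotation.
#' @param s,t grids passed to [gen_curvature_wave()].
#' @param pivot tethering point (um).
#' @param skip_points number of proximal arclength nodes omitted from the
#'   returned tracks.  The flagellar base (s = 0) sits exactly at the
#'   tethering point and rotates rigidly; dropping it mirrors recordings in
#'   which the first tracked flagellar point lies distal of the tether, so
#'   the pivot-to-first-point angle is defined and carries the beat wobble.
#' @param seed RNG seed for waveform noise.
#' @return a [flagellum_tracks]; `attr(, "truth")` holds the waveform record
#'   plus the true rotation `Omega_t` and accumulated angle `rot_angle`.
#' @export
gen_rotating_cell <- function(spec, drift = NULL, omega_fun = 0,
                              s = seq(0, spec$L, by = 0.9),
                              t = seq(0, 10, by = 1 / 500),
                              pivot = c(0, 0), skip_points = 1, seed = 1) {
  if (is.numeric(omega_fun)) {
    om <- omega_fun[1]
    omega_fun <- function(tt) rep(om, length(tt))
  }
  Omega_t <- omega_fun(t)
  if (max(abs(Omega_t)) > 1) {
    warning("|Omega| above 1 rev/s; the rotation filter assumptions may fail")
  }
  cf <- gen_curvature_wave(spec, drift, s = s, t = t, seed = seed)
  rot_angle <- 2 * pi * cumtrapz(t, Omega_t)
  # base point at the pivot; theta0 = rot_angle rotates the whole frame
  # rigidly about it
  tracks <- integrate_shape(cf, pivot = c(0, 0), theta0 = rot_angle)
  tracks$x_um <- tracks$x_um + pivot[1]
  tracks$y_um <- tracks$y_um + pivot[2]
  if (skip_points > 0) {
    keep <- tracks$point_index > skip_points
    tracks <- tracks[keep, ]
    tracks$point_index <- tracks$point_index - skip_points
    class(tracks) <- c("flagellum_tracks", "data.frame")
  }
  attr(tracks, "pivot") <- pivot
  truth <- attr(cf, "truth")
  truth$Omega_t <- Omega_t
  truth$rot_angle <- rot_angle
  truth$field <- cf
  attr(tracks, "truth") <- truth
  tracks
}

#' Emulate frame-to-frame variation of the tracked length
#'
#' Real trackers lose a few distal points in some frames.  This drops a
#' random number (0 to `max_drop`) of tail points from each frame, producing
#' ragged tracks; apply [common_window()] to restore a shared point count.
#'
#' @param tracks a [flagellum_tracks].
#' @param max_drop maximum number of tail points dropped per frame.
#' @param seed RNG seed.
#' @return a ragged [flagellum_tracks].
#' @export
truncate_tail_points <- function(tracks, max_drop = 3, seed = 1) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  frames <- unique(tracks$frame)
  drops <- sample(0:max_drop, length(frames), replace = TRUE)
  counts <- table(tracks$frame)
  keep_n <- as.integer(counts) - drops[match(names(counts), frames)]
  keep <- tracks$point_index <= keep_n[match(tracks$frame, as.integer(names(counts)))]
  out <- tracks[keep, ]
  class(out) <- c("flagellum_tracks", "data.frame")
  attr(out, "pivot") <- attr(tracks, "pivot")
  out
}

#' Common-window rule for ragged tracks
#'
#' Keeps only the arclength window tracked in every frame: points beyond the
#' shortest per-frame point count are discarded.
#'
#' @param tracks a [flagellum_tracks] (possibly ragged).
#' @return a [flagellum_tracks] with a common point count per frame.
#' @export
common_window <- function(tracks) {
  counts <- table(tracks$frame)
  np <- min(counts)
  out <- tracks[tracks$point_index <= np, ]
  class(out) <- c("flagellum_tracks", "data.frame")
  attr(out, "pivot") <- attr(tracks, "pivot")
  out
}
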