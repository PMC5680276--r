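# Curvature field container plus the kinematic observables computed from
# tracked flagellar points: three-point curvature, cell rotation velocity,
# mirror-symmetry defect and sliding-window average curvature.

#' Curvature field C(s, t)
#'
#' The central container of the analysis pipeline: local flagellar curvature
#' on a fixed arclength/time grid.  The sign convention is positive for
#' counter-clockwise bends and negative for clockwise bends (with x rightward
#' and y upward).
#'
#' @param C numeric matrix, arclength (rows) by time (columns), 1/um.
#' @param s arclength grid (um), measured from the first tracking point.
#' @param t time grid (s).
#' @return an object of class `curvature_field` with elements `C`, `s`, `t`,
#'   `ds`, `dt` and `sign_convention`.
#' @export
curvature_field <- function(C, s, t) {
  C <- as.matrix(C)
  stopifnot(nrow(C) == length(s), ncol(C) == length(t))
  structure(list(
    C = C, s = as.numeric(s), t = as.numeric(t),
    ds = if (length(s) > 1) stats::median(diff(s)) else NA_real_,
    dt = if (length(t) > 1) stats::median(diff(t)) else NA_real_,
    sign_convention = "ccw_positive"
  ), class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf("Curvature field: %d arclength points x %d frames\n",
              nrow(x$C), ncol(x$C)))
  cat(sprintf("  s in [%.2f, %.2f] um (ds ~ %.3g), t in [%.3g, %.3g] s (%.0f fps)\n",
              min(x$s), max(x$s), x$ds, min(x$t), max(x$t), 1 / x$dt))
  cat(sprintf("  curvature rms %.4g 1/um, sign: %s\n",
              sqrt(mean(x$C^2)), x$sign_convention))
  invisible(x)
}

#' Kymograph plot of a curvature field
#' @param x a [curvature_field].
#' @param ... passed to [graphics::image()].
#' @export
plot.curvature_field <- function(x, ...) {
  graphics::image(x$t, x$s, t(x$C), xlab = "time (s)", ylab = "arclength (um)",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"), ...)
  invisible(x)
}

#' Tracked flagellar point series
#'
#' Long-format table of tracked midline points, one row per frame and point,
#' ordered head to tip, with the head tethering point (pivot) stored as an
#' attribute.  All downstream modules consume this schema regardless of
#' whether the points come from the synthetic generator or the image tracker.
#'
#' @param frame integer frame index (1-based).
#' @param time_s time stamp (s).
#' @param point_index integer position along the flagellum (1 = head end).
#' @param x_um,y_um coordinates (um), x rightward, y upward.
#' @param pivot length-2 numeric, the tethering point (um).
#' @return a `data.frame` of class `flagellum_tracks`.
#' @export
flagellum_tracks <- function(frame, time_s, point_index, x_um, y_um,
                             pivot = c(0, 0)) {
  df <- data.frame(frame = as.integer(frame), time_s = time_s,
                   point_index = as.integer(point_index),
                   x_um = x_um, y_um = y_um)
  attr(df, "pivot") <- as.numeric(pivot)
  class(df) <- c("flagellum_tracks", "data.frame")
  df
}

# Reshape tracks with a common point count into npts x nframes matrices.
tracks_arrays <- function(tracks) {
  counts <- table(tracks$frame)
  if (length(unique(counts)) != 1L) {
    stop("tracks do not share a common point count across frames; ",
         "apply the common-window rule first")
  }
  np <- as.integer(counts[1])
  o <- order(tracks$frame, tracks$point_index)
  tr <- tracks[o, ]
  nf <- length(counts)
  list(
    x = matrix(tr$x_um, np, nf), y = matrix(tr$y_um, np, nf),
    t = tr$time_s[seq(1, nrow(tr), by = np)],
    pivot = attr(tracks, "pivot")
  )
}

#' Three-point curvature of tracked points
#'
#' The curvature at each interior point is the inverse radius of the
#' circumcircle through it and its two neighbours, signed by the orientation
#' of the triple: positive when the path bends counter-clockwise.  Endpoints
#' carry no curvature value, so a track of n points yields n - 2 curvature
#' samples; the arclength axis is measured from the first tracked point.
#'
#' @param tracks a [flagellum_tracks] with a common point count per frame.
#' @return a [curvature_field] on the interior points.
#' @export
curvature_three_point <- function(tracks) {
  a <- tracks_arrays(tracks)
  np <- nrow(a$x)
  if (np < 3L) stop("need at least 3 points per frame")
  i <- 2:(np - 1)
  ax <- a$x[i - 1, , drop = FALSE]; ay <- a$y[i - 1, , drop = FALSE]
  bx <- a$x[i, , drop = FALSE];     by <- a$y[i, , drop = FALSE]
  cx <- a$x[i + 1, , drop = FALSE]; cy <- a$y[i + 1, , drop = FALSE]
  # signed curvature = 2 * cross / (|ab| |bc| |ca|), cross > 0 for ccw triples
  ux <- bx - ax; uy <- by - ay
  vx <- cx - bx; vy <- cy - by
  wx <- cx - ax; wy <- cy - ay
  du <- sqrt(ux^2 + uy^2); dv <- sqrt(vx^2 + vy^2); dw <- sqrt(wx^2 + wy^2)
  if (any(du == 0) || any(dv == 0)) stop("duplicate points in track")
  cross <- ux * vy - uy * vx
  C <- 2 * cross / (du * dv * dw)   # collinear triples give exactly 0
  # arclength from the first tracked point, averaged over frames
  seg <- sqrt(diff(a$x[, 1])^2 + diff(a$y[, 1])^2)
  s_all <- c(0, cumsum(seg))
  curvature_field(C, s_all[i], a$t)
}

#' Rotation trace of a tethered cell
#'
#' The rotation angle alpha(t) is the angle between the x-axis and the vector
#' from the tethering point to the first tracked flagellar point.  It is
#' unwrapped, smoothed with a Gaussian filter (SD `filter_width`, truncated
#' at 3 SD) to remove the fast beat oscillation, and differentiated by
#' central differences.  The rotation velocity Omega is reported in
#' revolutions per second, positive for counter-clockwise rotation.
#'
#' @param tracks a [flagellum_tracks]; the pivot attribute is the tethering
#'   point.
#' @param filter_width Gaussian filter SD (s).
#' @return an object of class `rotation_trace`: data.frame columns `t`,
#'   `alpha` (unwrapped, filtered, rad) and `Omega` (rev/s), with the filter
#'   width as an attribute.
#' @export
rotation_velocity <- function(tracks, filter_width = 1.0) {
  a <- tracks_arrays(tracks)
  dx <- a$x[1, ] - a$pivot[1]
  dy <- a$y[1, ] - a$pivot[2]
  if (any(dx == 0 & dy == 0)) {
    stop("pivot coincides with the first tracked point")
  }
  dt <- stats::median(diff(a$t))
  if (filter_width > 0 && diff(range(a$t)) < 2 * filter_width) {
    stop("record shorter than twice the filter width")
  }
  alpha <- unwrap_angle(atan2(dy, dx))
  alpha_f <- gaussian_smooth(alpha, dt, filter_width)
  Omega <- central_diff(alpha_f, dt) / (2 * pi)
  structure(data.frame(t = a$t, alpha = alpha_f, Omega = Omega),
            filter_width = filter_width,
            class = c("rotation_trace", "data.frame"))
}

#' Half-period mirror-symmetry defect
#'
#' A beat with a single frequency obeys C(s, t) = -C(s, t + tau/2): after
#' half a period the waveform is its own mirror image.  The defect quantifies
#' the violation of this antisymmetry as
#' `||C(s,t) + C(s,t+tau/2)||_2 / (2 ||C||_2)` over all available pairs.
#' For a noise-free two-harmonic wave with zero offset the defect equals
#' `C2 / sqrt(C1^2 + C2^2)`; it approaches 1 as a static offset dominates.
#'
#' @param field a [curvature_field].
#' @param tau beat period (s); estimate it with [spectrogram_harmonics()].
#' @return scalar in `[0, 1]`.
#' @export
mirror_symmetry_defect <- function(field, tau) {
  dt <- field$dt
  lag <- round((tau / 2) / dt)
  if (lag < 1) stop("beat period not resolvable at this frame rate")
  nt <- ncol(field$C)
  if (nt - lag < lag) stop("record shorter than 1.5 beat periods")
  A <- field$C[, 1:(nt - lag), drop = FALSE]
  B <- field$C[, (lag + 1):nt, drop = FALSE]
  sqrt(mean((A + B)^2)) / (2 * sqrt(mean(field$C^2)))
}

#' Sliding-window average curvature C0(t)
#'
#' Mean curvature over arclength and a sliding time window, evaluated on the
#' same cadence as the harmonic spectrogram so the offset trace can be laid
#' over the second-harmonic intensity.
#'
#' @param field a [curvature_field].
#' @param window window length (s); should cover at least one beat period so
#'   the oscillatory part averages out.
#' @param step_frames cadence of window centres (frames).
#' @return data.frame with columns `t` (window centre, s) and `C0` (1/um).
#' @export
average_curvature <- function(field, window = 0.5, step_frames = 30) {
  W <- round(window / field$dt)
  nt <- ncol(field$C)
  if (W > nt) stop("window longer than the record")
  centers <- seq(ceiling(W / 2), nt - floor(W / 2), by = step_frames)
  colmean <- colMeans(field$C)
  C0 <- vapply(centers, function(i) {
    idx <- (i - floor(W / 2) + 1):(i - floor(W / 2) + W)
    mean(colmean[idx])
  }, numeric(1))
  data.frame(t = field$t[centers], C0 = C0)
}
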