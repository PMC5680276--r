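# Rendering of synthetic dark-field-like image stacks: a bright filament
# ridge plus a bright head blob on a dark background, with Gaussian
# line-spread and additive noise.  Only ridge geometry matters to the
# tracker, so no attempt is made at photometric realism.

#' Render tracked points into a synthetic image stack
#'
#' Each frame accumulates a Gaussian line-spread along a densely resampled
#' filament polyline and a Gaussian-tapered ellipse for the head centred on
#' the pivot.  Pixel centres sit at half-integer coordinates; image row 1 is
#' the top of the field, and conversion to micrometres flips the y-axis so
#' that y points upward (counter-clockwise positive).
#'
#' @param tracks a [flagellum_tracks].
#' @param pixel_um pixel size (um/px).
#' @param fov field of view (um), scalar (square) or c(width, height); the
#'   field is centred on the bounding box of all points.  Warns when the
#'   resampling step falls below one pixel.
#' @param psf_sigma_um Gaussian line-spread SD (um).
#' @param head_axes head ellipse semi-axes (um), `c(a, b)`; `NULL` omits the
#'   head.
#' @param head_intensity peak head intensity relative to the filament ridge.
#' @param snr ridge amplitude over noise SD; `Inf` for noise-free frames.
#' @param seed RNG seed for the noise.
#' @return object of class `synthetic_scene`: list with `frames` (H x W x
#'   n array, ridge amplitude 1), `pixel_um`, `frame_interval`, `origin_um`
#'   (um position of the image's top-left corner), `truth` (the input
#'   tracks), `head` (centre/axes/orientation per frame).
#' @export
render_frames <- function(tracks, pixel_um = 0.5, fov = NULL,
                          psf_sigma_um = 0.6, head_axes = c(2.5, 1.5),
                          head_intensity = 2, snr = 20, seed = 1) {
  pivot <- attr(tracks, "pivot")
  by_frame <- split(tracks[, c("x_um", "y_um")], tracks$frame)
  t_all <- tracks$time_s[!duplicated(tracks$frame)]
  pad <- 5 + if (!is.null(head_axes)) max(head_axes) else 0
  xr <- range(tracks$x_um, pivot[1]) + c(-pad, pad)
  yr <- range(tracks$y_um, pivot[2]) + c(-pad, pad)
  if (!is.null(fov)) {
    fov <- rep_len(fov, 2)
    cx <- mean(xr); cy <- mean(yr)
    xr <- cx + c(-fov[1], fov[1]) / 2
    yr <- cy + c(-fov[2], fov[2]) / 2
  }
  W <- ceiling(diff(xr) / pixel_um)
  H <- ceiling(diff(yr) / pixel_um)
  p1 <- by_frame[[1]]
  ds_track <- stats::median(sqrt(diff(p1$x_um)^2 + diff(p1$y_um)^2))
  if (ds_track < pixel_um) {
    warning("pixel size coarser than the point spacing; ridge undersampled")
  }
  nf <- length(by_frame)
  frames <- array(0, c(H, W, nf))
  # pixel-centre coordinate grids (um), y up
  px_x <- xr[1] + (seq_len(W) - 0.5) * pixel_um
  px_y <- yr[2] - (seq_len(H) - 0.5) * pixel_um
  sig <- psf_sigma_um
  half <- ceiling(3 * sig / pixel_um)
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  # head orientation from the first tracked point of each frame
  head_or <- vapply(by_frame, function(p) {
    atan2(p$y_um[1] - pivot[2], p$x_um[1] - pivot[1])
  }, numeric(1))
  for (f in seq_len(nf)) {
    img <- matrix(0, H, W)
    # dense polyline resample (step ~ sig/2) for a smooth ridge
    xs <- by_frame[[f]]$x_um; ys <- by_frame[[f]]$y_um
    seg <- sqrt(diff(xs)^2 + diff(ys)^2)
    cum <- c(0, cumsum(seg))
    dense <- seq(0, cum[length(cum)], by = sig / 2)
    dx <- stats::approx(cum, xs, xout = dense)$y
    dy <- stats::approx(cum, ys, xout = dense)$y
    wgt <- rep(1, length(dense))
    # accumulate max over dense Gaussian blobs -> constant-height ridge
    for (p in seq_along(dense)) {
      ic <- round((dx[p] - xr[1]) / pixel_um + 0.5)
      ir <- round((yr[2] - dy[p]) / pixel_um + 0.5)
      rows <- max(1, ir - half):min(H, ir + half)
      cols <- max(1, ic - half):min(W, ic + half)
      if (!length(rows) || !length(cols)) next
      d2 <- outer((px_y[rows] - dy[p])^2, (px_x[cols] - dx[p])^2, `+`)
      g <- wgt[p] * exp(-d2 / (2 * sig^2))
      img[rows, cols] <- pmax(img[rows, cols], g)
    }
    if (!is.null(head_axes)) {
      hc <- pivot
      co <- cos(head_or[f]); so <- sin(head_or[f])
      hw <- ceiling((max(head_axes) + 3 * sig) / pixel_um)
      ic <- round((hc[1] - xr[1]) / pixel_um + 0.5)
      ir <- round((yr[2] - hc[2]) / pixel_um + 0.5)
      rows <- max(1, ir - hw):min(H, ir + hw)
      cols <- max(1, ic - hw):min(W, ic + hw)
      XX <- outer(rep(1, length(rows)), px_x[cols] - hc[1])
      YY <- outer(px_y[rows] - hc[2], rep(1, length(cols)))
      u <- (XX * co + YY * so) / head_axes[1]
      v <- (-XX * so + YY * co) / head_axes[2]
      q <- u^2 + v^2
      blob <- head_intensity * ifelse(q <= 1, 1, exp(-(sqrt(q) - 1)^2 *
                                                       min(head_axes)^2 / (2 * sig^2)))
      img[rows, cols] <- pmax(img[rows, cols], blob)
    }
    if (is.finite(snr)) {
      img <- img + matrix(stats::rnorm(H * W, sd = 1 / snr), H, W)
    }
    frames[, , f] <- img
  }
  structure(list(frames = frames, pixel_um = pixel_um,
                 frame_interval = stats::median(diff(t_all)),
                 t = t_all, origin_um = c(xr[1], yr[2]),
                 truth = tracks,
                 head = list(center = pivot, axes = head_axes,
                             orientation = head_or)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Synthetic scene: %d frames of %d x %d px (%.3g um/px, %.0f fps)\n",
              d[3], d[1], d[2], x$pixel_um, 1 / x$frame_interval))
  invisible(x)
}

#' Write a synthetic scene as a 16-bit TIFF stack plus JSON sidecar
#'
#' @param scene a `synthetic_scene`.
#' @param path output TIFF path; the sidecar is written next to it with
#'   extension `.json`.
#' @return invisibly, the two file paths.
#' @export
write_scene_tiff <- function(scene, path) {
  img <- scene$frames
  img <- img - min(img)
  img <- img / max(img)
  frames <- lapply(seq_len(dim(img)[3]), function(f) img[, , f])
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  meta <- list(pixel_um = scene$pixel_um,
               frame_interval = scene$frame_interval,
               origin_um = scene$origin_um)
  side <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (identical(side, path)) side <- paste0(path, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Read a TIFF stack written by [write_scene_tiff()]
#'
#' @param path TIFF path with an accompanying JSON sidecar.
#' @return a `synthetic_scene` (without ground truth).
#' @export
read_scene_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  side <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (!file.exists(side)) side <- paste0(path, ".json")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  arr <- array(unlist(frames), c(H, W, length(frames)))
  structure(list(frames = arr, pixel_um = meta$pixel_um,
                 frame_interval = meta$frame_interval,
                 t = (seq_along(frames) - 1) * meta$frame_interval,
                 origin_um = meta$origin_um, truth = NULL, head = NULL),
            class = "synthetic_scene")
}

#' Write tracked points to CSV (with optional ground-truth JSON sidecar)
#'
#' @param tracks a [flagellum_tracks].
#' @param path output CSV path.
#' @param truth write the `truth` attribute (if any) as a JSON sidecar.
#' @return invisibly, the CSV path.
#' @export
write_tracks_csv <- function(tracks, path, truth = FALSE) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  if (truth && !is.null(attr(tracks, "truth"))) {
    tr <- attr(tracks, "truth")
    keep <- tr[!vapply(tr, is.function, logical(1))]
    keep <- keep[!vapply(keep, function(x) inherits(x, "curvature_field"),
                         logical(1))]
    jsonlite::write_json(keep, sub("\\.csv$", "_truth.json", path),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  invisible(path)
}

#' Read tracked points from CSV
#' @param path CSV with columns frame, time_s, point_index, x_um, y_um.
#' @param pivot tethering point (um).
#' @return a [flagellum_tracks].
#' @export
read_tracks_csv <- function(path, pivot = c(0, 0)) {
  df <- utils::read.csv(path)
  flagellum_tracks(df$frame, df$time_s, df$point_index, df$x_um, df$y_um,
                   pivot = pivot)
}
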