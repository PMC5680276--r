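# Midline tracking of filament image stacks: adaptive binarisation by
# threshold descent, morphological thinning, path ordering from the head,
# sub-pixel refinement, and resampling to a fixed arclength step with the
# common-window rule across frames.

#' Adaptive binarisation by threshold descent
#'
#' Starting from the 99.5th intensity percentile, the threshold is lowered
#' by a multiplicative factor until the foreground area matches the
#' expected cell area within tolerance and the skeleton is at least as long
#' as the coarse expected flagellar length.
#'
#' @param frame numeric image matrix.
#' @param expected_area_um2 expected foreground (cell) area (um^2).
#' @param coarse_length_um coarse expected flagellar length (um); 0 skips
#'   the skeleton-length check.
#' @param pixel_um pixel size (um/px).
#' @param tol relative area tolerance.
#' @param decrement multiplicative threshold decrement per iteration.
#' @return logical mask with attributes `threshold` and `thresholds` (the
#'   descent actually taken).  Errors with "target area unreachable" when no
#'   threshold satisfies the tolerance.
#' @export
binarize_adaptive <- function(frame, expected_area_um2, coarse_length_um = 0,
                              pixel_um = 0.5, tol = 0.15, decrement = 0.98) {
  stopifnot(expected_area_um2 > 0,
            expected_area_um2 < length(frame) * pixel_um^2)
  thr <- stats::quantile(frame, 0.995, names = FALSE)
  lo <- min(frame)
  px_area <- pixel_um^2
  taken <- numeric(0)
  while (thr > lo) {
    taken <- c(taken, thr)
    mask <- frame >= thr
    area <- sum(mask) * px_area
    if (area > expected_area_um2 * (1 + tol)) break     # overshot: give up
    if (area >= expected_area_um2 * (1 - tol)) {
      if (coarse_length_um > 0) {
        skel <- thin_mask(mask)
        if (sum(skel) * pixel_um < coarse_length_um * (1 - tol)) {
          thr <- thr * decrement
          next
        }
      }
      return(structure(mask, threshold = thr, thresholds = taken))
    }
    thr <- thr * decrement
  }
  stop("target area unreachable")
}

# Zhang-Suen morphological thinning of a logical mask, vectorised over the
# image.  Returns a 1-px-wide 8-connected skeleton.
thin_mask <- function(mask) {
  M <- mask
  H <- nrow(M); W <- ncol(M)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- M
  shift <- function(P, dr, dc) P[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      P2 <- shift(pad, -1, 0);  P3 <- shift(pad, -1, 1)
      P4 <- shift(pad, 0, 1);   P5 <- shift(pad, 1, 1)
      P6 <- shift(pad, 1, 0);   P7 <- shift(pad, 1, -1)
      P8 <- shift(pad, 0, -1);  P9 <- shift(pad, -1, -1)
      Bn <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      cur <- pad[2:(H + 1), 2:(W + 1)]
      if (pass == 1) {
        cond <- cur & Bn >= 2 & Bn <= 6 & A == 1 &
          !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- cur & Bn >= 2 & Bn <= 6 & A == 1 &
          !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) {
        cur[cond] <- FALSE
        pad[2:(H + 1), 2:(W + 1)] <- cur
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(H + 1), 2:(W + 1)]
}

# Fill interior holes of a mask: background is flood-filled (4-connected)
# from the image border by iterative dilation; unreached background pixels
# are holes.
fill_holes <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, H, W)
  reach[1, ] <- bg[1, ]; reach[H, ] <- bg[H, ]
  reach[, 1] <- bg[, 1]; reach[, W] <- bg[, W]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-H, ]
    grown[-H, ] <- grown[-H, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -W]
    grown[, -W] <- grown[, -W] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | !reach
}

# 8-neighbour offsets, orthogonal neighbours first (preferred when walking
# a skeleton so that staircase diagonals do not shortcut past a pixel)
.nbr8 <- cbind(dr = c(-1, 0, 0, 1, -1, -1, 1, 1),
               dc = c(0, -1, 1, 0, -1, 1, -1, 1))

# Connected-component labelling (8-connectivity) by flood fill.
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nextlab <- 0L
  idx <- which(mask)
  H <- nrow(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% H + 1L
      cc <- (p - 1L) %/% H + 1L
      for (k in 1:8) {
        rr <- r + .nbr8[k, 1]; cc2 <- cc + .nbr8[k, 2]
        if (rr >= 1 && rr <= H && cc2 >= 1 && cc2 <= ncol(mask)) {
          q <- (cc2 - 1L) * H + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nextlab
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  lab
}

#' Skeletonise a mask and order the flagellar path from the head
#'
#' Thins the (hole-filled) mask to a 1-px skeleton, removes the part inside
#' the head ellipse, and extracts the flagellar midline as the longest
#' geodesic from the head-proximal skeleton pixel: a breadth-first search
#' over the 8-connected skeleton graph whose farthest leaf is the tip.
#' Spur pixels off the geodesic are discarded; if any discarded side branch
#' is longer than `prune_um`, the topology is considered ambiguous.
#'
#' @param mask logical mask.
#' @param head a `head_pose` (see [fit_head_ellipse()]) or a list with
#'   `center` (px, row/col) and `radius_px`; used both to exclude head
#'   pixels and to pick the proximal endpoint.
#' @param prune_um spur prune length (um).
#' @param pixel_um pixel size (um/px).
#' @return integer matrix (n x 2, columns row/col) of ordered skeleton
#'   pixels.  Errors: "no flagellum" when nothing remains, "ambiguous
#'   topology" when branches survive pruning.
#' @export
skeletonize_and_order <- function(mask, head, prune_um = 2, pixel_um = 0.5) {
  skel <- thin_mask(fill_holes(mask))
  # remove head-interior pixels (slightly dilated ellipse)
  if (!is.null(head)) {
    rr <- row(skel); cc <- col(skel)
    co <- cos(head$orientation); so <- sin(head$orientation)
    dx <- cc - head$center[2]; dy <- -(rr - head$center[1])  # y up
    u <- (dx * co + dy * so) / (head$axes_px[1] + 1)
    v <- (-dx * so + dy * co) / (head$axes_px[2] + 1)
    skel[u^2 + v^2 <= 1] <- FALSE
  }
  if (!any(skel)) stop("no flagellum")
  lab <- label_components(skel)
  sizes <- tabulate(lab[lab > 0])
  skel <- lab == which.max(sizes)
  H <- nrow(skel)
  idx <- which(skel)
  pr <- (idx - 1L) %% H + 1L
  pc <- (idx - 1L) %/% H + 1L
  pos <- match(seq_len(length(skel)), idx)   # pixel id -> node index
  # adjacency lists over the skeleton graph
  nbrs <- lapply(seq_along(idx), function(i) {
    out <- integer(0)
    for (k in 1:8) {
      rr <- pr[i] + .nbr8[k, 1]; c2 <- pc[i] + .nbr8[k, 2]
      if (rr >= 1 && rr <= H && c2 >= 1 && c2 <= ncol(skel)) {
        j <- pos[(c2 - 1L) * H + rr]
        if (!is.na(j)) out <- c(out, j)
      }
    }
    out
  })
  bfs <- function(from) {
    dist <- rep(NA_integer_, length(idx))
    parent <- rep(0L, length(idx))
    dist[from] <- 0L
    queue <- from
    qh <- 1L
    while (qh <= length(queue)) {
      v <- queue[qh]; qh <- qh + 1L
      for (w in nbrs[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          parent[w] <- v
          queue[length(queue) + 1L] <- w
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  d_head <- sqrt((pr - head$center[1])^2 + (pc - head$center[2])^2)
  start <- which.min(d_head)
  b <- bfs(start)
  tip <- which.max(b$dist)
  path <- tip
  while (path[1] != start) path <- c(b$parent[path[1]], path)
  # side branches off the geodesic: tolerated up to the prune length
  off <- setdiff(seq_along(idx), path)
  if (length(off)) {
    keep <- matrix(FALSE, H, ncol(skel))
    keep[idx[off]] <- TRUE
    offlab <- label_components(keep)
    if (max(tabulate(offlab[offlab > 0])) > ceiling(prune_um / pixel_um)) {
      stop("ambiguous topology")
    }
  }
  cbind(row = pr[path], col = pc[path])
}

#' Fit the head ellipse
#'
#' Segments the head as the largest bright blob (intensity above
#' `intensity_frac` of the maximum), and fits an ellipse by second moments:
#' semi-axes are `2 * sqrt(eigenvalues)` of the pixel covariance, the
#' orientation is the leading eigenvector, and the tethering point is the
#' centroid.
#'
#' @param frame numeric image matrix.
#' @param intensity_frac threshold as a fraction of the frame maximum.
#' @param min_area_px minimum blob area (px); below it, error "no head".
#' @param pixel_um pixel size (um/px).
#' @return object of class `head_pose`: `center` (px, row/col), `center_um`
#'   (um, x/y with y up assuming the frame's top-left origin), `axes_px`,
#'   `axes_um` (semi-axes), `orientation` (rad), `degenerate` (TRUE for a
#'   near-circular blob, orientation reported as 0).
#' @export
fit_head_ellipse <- function(frame, intensity_frac = 0.7, min_area_px = 20,
                             pixel_um = 0.5) {
  if (diff(range(frame)) == 0) stop("no head")
  mask <- frame >= intensity_frac * max(frame)
  if (!any(mask)) stop("no head")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  blob <- lab == which.max(sizes)
  if (sum(blob) < min_area_px) stop("no head")
  rr <- row(blob)[blob]; cc <- col(blob)[blob]
  # centroid and second moments in (x right, y up) pixel coordinates
  xs <- cc - 0.5; ys <- nrow(frame) - rr + 0.5
  mx <- mean(xs); my <- mean(ys)
  Cov <- stats::cov(cbind(xs, ys)) + diag(1 / 12, 2)  # pixel quantisation
  eg <- eigen(Cov, symmetric = TRUE)
  axes_px <- 2 * sqrt(pmax(eg$values, 0))
  degenerate <- diff(range(axes_px)) < 0.05 * mean(axes_px)
  orientation <- if (degenerate) 0 else atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  structure(list(center = c(mean(rr), mean(cc)),
                 center_um = c(mx, my) * pixel_um,
                 axes_px = axes_px, axes_um = axes_px * pixel_um,
                 orientation = orientation, degenerate = degenerate),
            class = "head_pose")
}

# Sub-pixel refinement: move each path point to the intensity-weighted
# centroid across the local normal (window +/- 2 px).
subpixel_refine <- function(frame, path_rc, window = 2) {
  n <- nrow(path_rc)
  out <- matrix(NA_real_, n, 2)
  H <- nrow(frame); W <- ncol(frame)
  for (i in seq_len(n)) {
    j0 <- max(1, i - 2); j1 <- min(n, i + 2)
    tv <- c(path_rc[j1, 1] - path_rc[j0, 1], path_rc[j1, 2] - path_rc[j0, 2])
    tv <- tv / sqrt(sum(tv^2))
    nv <- c(-tv[2], tv[1])
    offs <- seq(-window, window, by = 0.5)
    rr <- path_rc[i, 1] + offs * nv[1]
    cc <- path_rc[i, 2] + offs * nv[2]
    ri <- round(rr); ci <- round(cc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    if (sum(ok) < 3) { out[i, ] <- path_rc[i, ]; next }
    wts <- frame[cbind(ri[ok], ci[ok])]
    wts <- pmax(wts - min(wts), 0)
    if (sum(wts) <= 0) { out[i, ] <- path_rc[i, ]; next }
    d <- sum(offs[ok] * wts) / sum(wts)
    out[i, ] <- path_rc[i, ] + d * nv
  }
  out
}

#' Track a movie of a beating flagellum
#'
#' Runs binarisation, head fitting, skeleton ordering and sub-pixel
#' refinement on every frame, resamples each midline at the arclength step
#' `ds`, and truncates all frames to the common tracked arclength window
#' (the part of the flagellum tracked in every frame).  Arclength is
#' measured from the first tracking point.
#'
#' @param scene a `synthetic_scene` (or any list with `frames`, `pixel_um`,
#'   `frame_interval`, `origin_um`).
#' @param expected_area_um2 expected cell area for [binarize_adaptive()];
#'   `NULL` estimates it from the first frame's bright area.
#' @param coarse_length_um coarse flagellar length (um).
#' @param ds resampling step (um).
#' @param prune_um spur prune length (um).
#' @param max_fail_frac abort when more than this fraction of frames fails.
#' @param smooth_df degrees of freedom of the per-frame smoothing spline
#'   applied to x(s), y(s) before resampling (0 disables smoothing).
#' @return a [flagellum_tracks] with the head centroid as pivot; per-frame
#'   failures (if any, up to `max_fail_frac`) are filled from the nearest
#'   tracked frame and listed in `attr(, "failed_frames")`.
#' @export
track_movie <- function(scene, expected_area_um2 = NULL,
                        coarse_length_um = 30, ds = 0.9, prune_um = 2,
                        max_fail_frac = 0.05, smooth_df = 12) {
  nf <- dim(scene$frames)[3]
  if (nf < 2) stop("need at least 2 frames")
  px <- scene$pixel_um
  if (is.null(expected_area_um2)) {
    # head + flagellar ribbon: pixels above a quarter of the peak intensity
    # (the head is rendered brighter than the ridge, so a high cut would
    # miss the flagellum entirely)
    f1 <- scene$frames[, , 1]
    expected_area_um2 <- sum(f1 >= 0.25 * max(f1)) * px^2
  }
  per_frame <- vector("list", nf)
  fails <- character(0)
  for (f in seq_len(nf)) {
    res <- tryCatch({
      frame <- scene$frames[, , f]
      mask <- binarize_adaptive(frame, expected_area_um2,
                                coarse_length_um = coarse_length_um,
                                pixel_um = px)
      head <- fit_head_ellipse(frame, pixel_um = px)
      path <- skeletonize_and_order(mask, head, prune_um = prune_um,
                                    pixel_um = px)
      subpixel_refine(frame, path)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fails <- c(fails, sprintf("frame %d: %s", f, res))
    } else {
      per_frame[[f]] <- res
    }
  }
  if (length(fails) > max_fail_frac * nf) {
    stop("tracking failed on ", length(fails), " of ", nf, " frames:\n",
         paste(utils::head(fails, 10), collapse = "\n"))
  }
  ok_frames <- which(!vapply(per_frame, is.null, logical(1)))
  for (f in seq_len(nf)[-ok_frames]) {
    per_frame[[f]] <- per_frame[[ok_frames[which.min(abs(ok_frames - f))]]]
  }
  # convert to um (y up), resample at ds, record arclength extents
  H <- dim(scene$frames)[1]
  to_um <- function(rc) {
    cbind(x = scene$origin_um[1] + (rc[, 2] - 0.5) * px,
          y = scene$origin_um[2] - (rc[, 1] - 0.5) * px)
  }
  # anchor the arclength origin at a fixed distance from the head centre:
  # the raw skeleton start jitters with the beat phase, which would
  # modulate every downstream arclength-indexed quantity coherently with
  # the beat
  head0 <- fit_head_ellipse(scene$frames[, , 1], pixel_um = px)
  pivot <- c(scene$origin_um[1] + head0$center_um[1],
             scene$origin_um[2] - (H * px - head0$center_um[2]))
  r0 <- max(head0$axes_um) + 1
  resampled <- lapply(seq_len(nf), function(f) {
    xy <- to_um(per_frame[[f]])
    d_head <- sqrt((xy[, 1] - pivot[1])^2 + (xy[, 2] - pivot[2])^2)
    i0 <- which(d_head >= r0)[1]
    if (is.na(i0)) i0 <- 1L
    if (i0 > 1L) {
      # interpolate the exact crossing of the r0 circle
      w <- (r0 - d_head[i0 - 1]) / (d_head[i0] - d_head[i0 - 1])
      p0 <- xy[i0 - 1, ] + w * (xy[i0, ] - xy[i0 - 1, ])
      xy <- rbind(p0, xy[i0:nrow(xy), , drop = FALSE])
    }
    resample_path(xy, ds = ds, smooth_df = smooth_df)
  })
  np <- min(vapply(resampled, nrow, integer(1)))   # common-window rule
  t_s <- (seq_len(nf) - 1) * scene$frame_interval
  tracks <- flagellum_tracks(
    frame = rep(seq_len(nf), each = np),
    time_s = rep(t_s, each = np),
    point_index = rep(seq_len(np), nf),
    x_um = unlist(lapply(resampled, function(m) m[1:np, 1])),
    y_um = unlist(lapply(resampled, function(m) m[1:np, 2])),
    pivot = pivot
  )
  attr(tracks, "failed_frames") <- fails
  tracks
}


# Resample a polyline at a fixed arclength step, optionally smoothing x and
# y as functions of cumulative chord length first.  Total arclength is
# preserved (up to the trailing partial step and the roughness removed by
# the smoother).
resample_path <- function(xy, ds = 0.9, smooth_df = 12) {
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  cum <- c(0, cumsum(seg))
  sg <- seq(0, cum[length(cum)], by = ds)
  if (smooth_df > 0 && length(cum) > smooth_df) {
    fx <- stats::smooth.spline(cum, xy[, 1], df = smooth_df)
    fy <- stats::smooth.spline(cum, xy[, 2], df = smooth_df)
    cbind(stats::predict(fx, sg)$y, stats::predict(fy, sg)$y)
  } else {
    cbind(stats::approx(cum, xy[, 1], xout = sg)$y,
          stats::approx(cum, xy[, 2], xout = sg)$y)
  }
}
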