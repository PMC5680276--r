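# Image rendering and midline tracking: binarisation, head pose, skeleton
# ordering, full-movie tracking with the common-window rule.

test_that("adaptive binarisation reaches the target area or refuses", {
  scene <- ref_scene(seconds = 0.06, snr = Inf)
  f1 <- scene$frames[, , 1]
  expected <- sum(f1 >= 0.25 * max(f1)) * scene$pixel_um^2
  mask <- binarize_adaptive(f1, expected, coarse_length_um = 30,
                            pixel_um = scene$pixel_um)
  area <- sum(mask) * scene$pixel_um^2
  expect_lt(abs(area - expected) / expected, 0.15)
  # thresholds strictly decrease during the descent
  expect_true(all(diff(attr(mask, "thresholds")) < 0))
  # the mask covers the true midline (within one pixel of dilation)
  truth <- attr(scene$truth, "pivot")
  tr <- scene$truth
  px <- scene$pixel_um
  cols <- pmin(pmax(round((tr$x_um - scene$origin_um[1]) / px + 0.5), 1),
               ncol(mask))
  rows <- pmin(pmax(round((scene$origin_um[2] - tr$y_um) / px + 0.5), 1),
               nrow(mask))
  first <- tr$frame == 1
  dil <- flagbeat:::fill_holes(mask)  # mask itself; check neighbourhood
  covered <- vapply(which(first), function(i) {
    r <- rows[i]; c <- cols[i]
    any(mask[max(1, r - 1):min(nrow(mask), r + 1),
             max(1, c - 1):min(ncol(mask), c + 1)])
  }, logical(1))
  expect_true(all(covered))
  # a uniformly dark frame has no reachable target area
  expect_error(binarize_adaptive(matrix(0.01, 50, 50), 25, 0, 0.5),
               "target area unreachable")
})

test_that("head ellipse recovery, degenerate circles and missing heads", {
  # sharply rendered ellipse, semi-axes 2.5 x 1.5 um at 0.25 um/px;
  # image rows run top to bottom, so y decreases with the row index
  px <- 0.25
  xs <- seq(-6, 6, by = px)
  ys_down <- seq(6, -6, by = -px)
  XX <- outer(rep(1, length(ys_down)), xs)
  YY <- outer(ys_down, rep(1, length(xs)))
  th0 <- 0.5
  u <- (XX * cos(th0) + YY * sin(th0)) / 2.5
  v <- (-XX * sin(th0) + YY * cos(th0)) / 1.5
  img <- (u^2 + v^2 <= 1) * 1
  pose <- fit_head_ellipse(img, pixel_um = px)
  expect_equal(sort(pose$axes_um), c(1.5, 2.5), tolerance = 0.1)
  expect_false(pose$degenerate)
  ang_err <- abs(flagbeat:::wrap_angle(pose$orientation - th0))
  expect_lt(min(ang_err, abs(ang_err - pi)), 0.1)
  # circle: orientation undefined, flagged degenerate, reported as 0
  imgc <- (XX^2 + YY^2 <= 4) * 1
  posec <- fit_head_ellipse(imgc, pixel_um = px)
  expect_true(posec$degenerate)
  expect_identical(posec$orientation, 0)
  # empty frame
  expect_error(fit_head_ellipse(matrix(0, 20, 20)), "no head")
})

test_that("skeleton ordering: straight lines, arcs, branches, no flagellum", {
  # straight horizontal ribbon
  mask <- matrix(FALSE, 40, 80)
  mask[19:21, 10:70] <- TRUE
  head <- list(center = c(20, 8), axes_px = c(3, 2), orientation = 0)
  path <- skeletonize_and_order(mask, head, pixel_um = 0.5)
  expect_true(all(abs(path[, 1] - 20) <= 1))          # collinear within 1 px
  expect_lt(abs(path[1, 2] - 10), 6)                  # starts at the head end
  expect_gt(nrow(path), 50)
  # circular arc: recovered arclength within 3% of the true arc
  H <- 120; W <- 120
  rr <- row(matrix(0, H, W)); cc <- col(matrix(0, H, W))
  rad <- sqrt((rr - 60)^2 + (cc - 60)^2)
  ang <- atan2(rr - 60, cc - 60)
  arc <- rad >= 38 & rad <= 41 & ang > -2 & ang < 1.1
  headc <- list(center = c(60 + 40 * sin(-2), 60 + 40 * cos(-2)),
                axes_px = c(3, 2), orientation = 0)
  # blunt end caps of a thick arc thin into short end spurs: a slightly
  # larger prune length absorbs them
  patha <- skeletonize_and_order(arc, headc, prune_um = 4, pixel_um = 0.5)
  seg <- sqrt(diff(patha[, 1])^2 + diff(patha[, 2])^2)
  true_arc <- 39.5 * 3.1
  expect_lt(abs(sum(seg) - true_arc) / true_arc, 0.03)
  # Y branch: ambiguous
  ym <- matrix(FALSE, 60, 60)
  ym[30, 5:40] <- TRUE
  ym[30:50, 40] <- TRUE
  ym[10:30, 40] <- TRUE
  heady <- list(center = c(30, 3), axes_px = c(2, 2), orientation = 0)
  expect_error(skeletonize_and_order(ym, heady, pixel_um = 0.5),
               "ambiguous topology")
  # head-only mask: nothing outside the head ellipse
  hm <- matrix(FALSE, 40, 40)
  hm[18:22, 18:22] <- TRUE
  headh <- list(center = c(20, 20), axes_px = c(6, 6), orientation = 0)
  expect_error(skeletonize_and_order(hm, headh, pixel_um = 0.5),
               "no flagellum")
})

test_that("path resampling preserves arclength within 1%", {
  # beat-like path: 4 um amplitude over a 40 um wavelength
  tseq <- seq(0, 36, by = 0.2)
  xy <- cbind(tseq, 4 * sin(2 * pi * tseq / 40))
  len_in <- sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
  out <- flagbeat:::resample_path(xy, ds = 0.9, smooth_df = 0)
  len_out <- sum(sqrt(diff(out[, 1])^2 + diff(out[, 2])^2))
  expect_lt(abs(len_out - len_in) / len_in, 0.01)
  # the optional smoother trims roughness but stays close
  outs <- flagbeat:::resample_path(xy, ds = 0.9, smooth_df = 12)
  lens <- sum(sqrt(diff(outs[, 1])^2 + diff(outs[, 2])^2))
  expect_lt(abs(lens - len_in) / len_in, 0.02)
})

test_that("noiseless movies are tracked to sub-half-pixel accuracy", {
  scene <- ref_scene(seconds = 0.12, snr = Inf)
  est <- track_movie(scene)
  expect_lt(tracks_rmse(est, scene$truth, every = 10), 0.3)
  # point spacing after resampling is ds within 10%
  a <- flagbeat:::tracks_arrays(est)
  seg <- sqrt(diff(a$x[, 1])^2 + diff(a$y[, 1])^2)
  expect_true(all(abs(seg - 0.9) < 0.09))
})

test_that("tracking is rotation-equivariant on noiseless scenes", {
  spec <- ref_spec(C2 = 0.015, phi = 0.8)
  t <- seq(0, 0.08, by = 1 / 500)
  tracks <- gen_rotating_cell(spec, NULL, omega_fun = 0,
                              s = seq(0, 36, by = 0.9), t = t,
                              skip_points = 3, seed = 2)
  rot90 <- tracks
  rot90$x_um <- -tracks$y_um
  rot90$y_um <- tracks$x_um
  attr(rot90, "pivot") <- c(-attr(tracks, "pivot")[2],
                            attr(tracks, "pivot")[1])
  e1 <- track_movie(render_frames(tracks, snr = Inf))
  e2 <- track_movie(render_frames(rot90, snr = Inf))
  # rotate the second result back and compare midlines as curves (the
  # discrete tracking start may shift by a fraction of a pixel, so
  # pointwise coordinates are only equal up to a tangential phase)
  back <- e2
  back$x_um <- e2$y_um
  back$y_um <- -e2$x_um
  attr(back, "pivot") <- c(attr(e2, "pivot")[2], -attr(e2, "pivot")[1])
  expect_lt(tracks_rmse(back, e1, every = 5), 0.1)
})

test_that("tail dropouts are healed by the common-window rule", {
  spec <- ref_spec(C2 = 0.015)
  t <- seq(0, 0.1, by = 1 / 500)
  tracks <- gen_rotating_cell(spec, NULL, omega_fun = 0, t = t,
                              skip_points = 3, seed = 2)
  ragged <- truncate_tail_points(tracks, max_drop = 3, seed = 9)
  counts <- table(ragged$frame)
  expect_gt(diff(range(counts)), 0)          # lengths really vary
  cw <- common_window(ragged)
  expect_equal(unname(unique(table(cw$frame))), min(counts))
  # the healed tracks feed the kinematics pipeline
  expect_s3_class(curvature_three_point(cw), "curvature_field")
  # a duplicated single frame tracks to identical rows
  one <- tracks[tracks$frame == 1, ]
  two <- one
  two$frame <- 2L
  dup <- rbind(one, two)
  class(dup) <- c("flagellum_tracks", "data.frame")
  attr(dup, "pivot") <- attr(tracks, "pivot")
  est <- track_movie(render_frames(dup, snr = Inf))
  a <- flagbeat:::tracks_arrays(est)
  expect_identical(a$x[, 1], a$x[, 2])
})

test_that("scenes round-trip through TIFF plus sidecar", {
  scene <- ref_scene(seconds = 0.06, snr = 20)
  tmp <- file.path(tempdir(), "scene.tif")
  write_scene_tiff(scene, tmp)
  back <- read_scene_tiff(tmp)
  expect_equal(dim(back$frames), dim(scene$frames))
  expect_equal(back$pixel_um, scene$pixel_um)
  # 16-bit quantisation: intensities match after rescaling
  a <- scene$frames - min(scene$frames)
  a <- a / max(a)
  expect_lt(max(abs(back$frames - a)), 1e-4)
  unlink(c(tmp, sub("\\.tif$", ".json", tmp)))
  # tracks round-trip through CSV
  tmp2 <- file.path(tempdir(), "tracks.csv")
  write_tracks_csv(scene$truth, tmp2)
  back2 <- read_tracks_csv(tmp2, pivot = attr(scene$truth, "pivot"))
  expect_equal(back2$x_um, scene$truth$x_um)
  unlink(tmp2)
})
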