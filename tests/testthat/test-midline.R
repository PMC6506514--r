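test_that("Zhang-Suen thinning matches an independent reference on canonical shapes", {
  shapes <- list()

  line <- matrix(0L, 7, 30); line[4, 3:28] <- 1L
  shapes$thin_line <- line

  rect <- matrix(0L, 9, 27); rect[4:6, 4:24] <- 1L   # 3 x 21 bar
  shapes$bar_3x21 <- rect

  disk <- matrix(0L, 17, 17)
  for (r in 1:17) for (c in 1:17)
    if ((r - 9)^2 + (c - 9)^2 <= 36) disk[r, c] <- 1L
  shapes$disk_r6 <- disk

  Lsh <- matrix(0L, 22, 22); Lsh[5:18, 5:7] <- 1L; Lsh[16:18, 5:18] <- 1L
  shapes$L_shape <- Lsh

  Ysh <- matrix(0L, 25, 25)
  Ysh[13:22, 12:14] <- 1L                       # stem
  for (i in 0:7) { Ysh[12 - i, 12 - i + (0:1)] <- 1L; Ysh[12 - i, 14 + i - (0:1)] <- 1L }
  shapes$Y_shape <- Ysh

  for (nm in names(shapes)) {
    expect_identical(skeletonize(shapes[[nm]]), ref_zhang_suen(shapes[[nm]]),
                     label = nm)
  }

  # an already-thin 8-connected line is returned unchanged
  expect_identical(skeletonize(line), line)

  # the 3 x 21 bar reduces to a 1-px centerline (ends erode <= 2 px each)
  sk <- skeletonize(rect)
  expect_true(all(which(sk == 1L, arr.ind = TRUE)[, 1] == 5))
  expect_gte(sum(sk), 17); expect_lte(sum(sk), 21)

  # a disk collapses to a few central pixels
  skd <- skeletonize(disk)
  expect_lte(sum(skd), 5)
  ctr <- which(skd == 1L, arr.ind = TRUE)
  expect_true(all(abs(ctr - 9) <= 2))

  expect_error(skeletonize(matrix(0L, 4, 4)), class = "gaitkin_bad_input")
})

test_that("skeleton output is thin and contained in the input", {
  cfg <- tiny_cfg()
  fr <- render_frame(midline_at_time(cfg, 0.02), cfg)
  mask <- binarize(fr, otsu_threshold(fr), "dark_fish")
  sk <- skeletonize(mask)
  expect_true(all(sk <= mask))        # subset of foreground
  expect_identical(sk, ref_zhang_suen(mask))
})

test_that("longest_path prunes spurs, matching exhaustive enumeration", {
  # straight line with a short spur
  m <- matrix(0L, 9, 36); m[5, 3:32] <- 1L; m[2:4, 17] <- 1L
  p <- longest_path(m)
  expect_equal(p$arc_length_px, ref_longest_path_length(m))
  expect_false(any(p$points[, 2] < 3))  # spur (rows 2:4 -> y 1:3) not taken

  # a simple path skeleton is returned identically (as a set, end to end)
  simple <- matrix(0L, 6, 20); simple[3, 2:18] <- 1L
  ps <- longest_path(simple)
  expect_equal(nrow(ps$points), 17)
  expect_equal(ps$arc_length_px, 16)

  # Y with arms 10, 10, 3: path runs through the two long arms
  y <- matrix(0L, 30, 30)
  y[15, 3:12] <- 1L          # arm 1 (10 px)
  y[15, 13:22] <- 1L         # arm 2 (10 px)
  y[12:14, 13] <- 1L         # short arm (3 px)
  expect_equal(longest_path(y)$arc_length_px, ref_longest_path_length(y))

  # cyclic skeleton (a ring) has no endpoints -> error
  ring <- matrix(0L, 8, 8)
  ring[3, 3:6] <- 1L; ring[6, 3:6] <- 1L; ring[4:5, 3] <- 1L; ring[4:5, 6] <- 1L
  expect_error(longest_path(ring), class = "gaitkin_cyclic_skeleton")
})

test_that("orientation puts the thick head end first and is direction-stable", {
  cfg <- tiny_cfg(duration_s = 0.06)
  v <- generate_video(cfg)
  gconf <- synth_gait_config(cfg)
  for (k in c(1, 15, 30)) {
    fr <- v$frames[[k]]
    mask <- binarize(fr, otsu_threshold(fr), "dark_fish")
    blob <- find_blobs(mask)[[1]]
    bb <- blob$bbox
    bmask <- matrix(0L, bb$height, bb$width)
    bmask[cbind(blob$pixels[, 2] - bb$y0 + 1, blob$pixels[, 1] - bb$x0 + 1)] <- 1L
    path <- longest_path(skeletonize(bmask))
    path$points[, 1] <- path$points[, 1] + bb$x0
    path$points[, 2] <- path$points[, 2] + bb$y0

    o1 <- orient_path(path, blob, policy = "thickness")
    # ground-truth head is the smaller-x end of the true midline
    gt_head <- v$midlines[[k]][1, ]
    d_head <- sum((o1$points[1, ] - gt_head)^2)
    d_tail <- sum((o1$points[nrow(o1$points), ] - gt_head)^2)
    expect_lt(d_head, d_tail)

    # reversing the input path yields the same oriented output
    rev_path <- path
    rev_path$points <- path$points[nrow(path$points):1, ]
    o2 <- orient_path(rev_path, blob, policy = "thickness")
    expect_equal(o1$points, o2$points)
  }
})

test_that("a symmetric dumbbell forces the fixed-direction fallback", {
  m <- matrix(0L, 15, 40)
  m[5:11, 3:9] <- 1L     # left knob
  m[5:11, 32:38] <- 1L   # right knob
  m[8, 10:31] <- 1L      # bar
  blob <- find_blobs(m)[[1]]
  path <- longest_path(skeletonize(m))
  expect_warning(o <- orient_path(path, blob, policy = "thickness",
                                  head_x_sign = -1),
                 "fixed_direction")
  expect_lt(o$points[1, 1], o$points[nrow(o$points), 1])
})

test_that("equidistant points split the path into equal arc-length thirds", {
  # straight path of arc length 30
  straight <- cbind(x = 0:30, y = rep(0, 31))
  pts <- equidistant_points(straight, 4)
  expect_equal(unname(pts),
               cbind(c(0, 10, 20, 30), c(0, 0, 0, 0)))

  # a 4-pixel path with equal steps returns the 4 pixel centers
  four <- cbind(x = c(0, 1, 2, 3), y = c(0, 1, 2, 3))
  expect_equal(unname(equidistant_points(four, 4)), unname(four))

  # quarter circle: points land at arc fractions of the closed-form angle
  r <- 40
  th <- seq(0, pi / 2, length.out = 2000)
  qc <- cbind(x = r * cos(th), y = r * sin(th))
  pts_c <- equidistant_points(qc, 4)
  for (i in 0:3) {
    ang <- (pi / 2) * i / 3
    expect_lt(sqrt(sum((pts_c[i + 1, ] - c(r * cos(ang), r * sin(ang)))^2)), 0.5)
  }

  expect_error(equidistant_points(straight, 1), class = "gaitkin_bad_input")
})

test_that("extracted midlines hug the true midline with equal A-D spacing", {
  cfg <- tiny_cfg(duration_s = 0.1)
  v <- generate_video(cfg)
  res <- analyze_video(v, synth_gait_config(cfg))
  fr <- res$trace$frames
  expect_true(all(fr$valid))
  n_ok <- 0
  for (k in seq_along(v$frames)) {
    pts <- matrix(c(fr$Ax[k], fr$Ay[k], fr$Bx[k], fr$By[k],
                    fr$Cx[k], fr$Cy[k], fr$Dx[k], fr$Dy[k]),
                  4, 2, byrow = TRUE)
    # A-D arc separations equal within one pixel step: check chord spacing
    d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    expect_lt(max(d) - min(d), 2 * sqrt(2))
    # directed Hausdorff (extracted points -> true midline)
    if (directed_hausdorff(pts, v$midlines[[k]]) <= 2) n_ok <- n_ok + 1
  }
  expect_gte(n_ok / length(v$frames), 0.95)
})
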