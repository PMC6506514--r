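test_that("percentile stretch and blur behave on degenerate and simple inputs", {
  # constant frame degenerates to all zeros
  expect_equal(preprocess_frame(matrix(120, 10, 10), gaussian_sigma = 0),
               matrix(0, 10, 10))

  # two-valued frame with full-range percentiles maps to {0, 255}
  f <- matrix(c(50, 200), 10, 10)
  out <- preprocess_frame(f, gaussian_sigma = 0, low_pct = 0, high_pct = 100)
  expect_setequal(unique(as.vector(out)), c(0, 255))

  # Gaussian blur preserves the total mass of an impulse (kernel sums to 1)
  imp <- matrix(0, 41, 41); imp[21, 21] <- 100
  bl <- preprocess_frame(imp, gaussian_sigma = 2, low_pct = 0, high_pct = 100)
  scale <- 255 / 100   # stretch maps 100 -> 255 first
  expect_equal(sum(bl), 100 * scale, tolerance = 0.005 * 100 * scale)

  expect_error(preprocess_frame(matrix(1, 2, 2), low_pct = 50, high_pct = 20),
               class = "gaitkin_bad_input")
})

test_that("preprocess and binarize are shift-invariant", {
  set.seed(1)
  base <- matrix(runif(30 * 30, 0, 255), 30, 30)
  big <- matrix(128, 50, 50); big[11:40, 11:40] <- base
  big2 <- matrix(128, 50, 50); big2[16:45, 6:35] <- base
  p1 <- preprocess_frame(big, gaussian_sigma = 0)
  p2 <- preprocess_frame(big2, gaussian_sigma = 0)
  expect_equal(p1[11:40, 11:40], p2[16:45, 6:35])
  b1 <- binarize(big, 100, "dark_fish")
  b2 <- binarize(big2, 100, "dark_fish")
  expect_equal(b1[11:40, 11:40], b2[16:45, 6:35])
})

test_that("otsu_threshold equals the exhaustive between-class-variance maximizer", {
  # bimodal half 0 / half 255
  v <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  expect_identical(otsu_threshold(v), ref_otsu(v))

  # two-valued image {50, 200}: t in [50, 199] and equal to the oracle
  v2 <- matrix(c(rep(50, 30), rep(200, 70)), 10, 10)
  t2 <- otsu_threshold(v2)
  expect_identical(t2, ref_otsu(v2))
  expect_gte(t2, 50); expect_lte(t2, 199)

  # property: random 8-bit images, several histogram shapes
  set.seed(20)
  for (i in 1:40) {
    img <- switch(1 + i %% 4,
      matrix(sample(0:255, 64, replace = TRUE), 8, 8),
      matrix(sample(0:40, 64, replace = TRUE), 8, 8),
      matrix(c(rnorm(32, 60, 12), rnorm(32, 190, 15)), 8, 8),
      matrix(rbeta(64, 0.4, 0.4) * 255, 8, 8))
    expect_identical(otsu_threshold(img), ref_otsu(img), label = paste("case", i))
  }

  expect_error(otsu_threshold(matrix(7, 4, 4)),
               class = "gaitkin_degenerate_histogram")
})

test_that("binarize respects polarity and reproduces a noiseless silhouette", {
  f <- matrix(c(10, 60, 200, 250), 2, 2)
  expect_equal(binarize(f, 255, "dark_fish"), matrix(1L, 2, 2))
  expect_equal(binarize(f, 100, "dark_fish") + binarize(f, 100, "bright_fish"),
               matrix(1L, 2, 2))  # complementary masks

  # noiseless synthetic frame + oracle Otsu -> mask equals the rendered fish
  cfg <- tiny_cfg()
  fr <- render_frame(midline_at_time(cfg, 0.013), cfg)
  thr <- otsu_threshold(fr)
  expect_identical(thr, ref_otsu(fr))
  mask <- binarize(fr, thr, "dark_fish")
  expect_identical(mask == 1L, fr == cfg$fish_intensity)
})

test_that("find_blobs detects 8-connected components with correct stats", {
  expect_identical(find_blobs(matrix(0L, 5, 5)), list())

  m <- matrix(0L, 20, 20)
  m[3:6, 2:11] <- 1L    # 10 x 4 rectangle, area 40
  m[12:14, 15:17] <- 1L # 3 x 3 square, area 9
  blobs <- find_blobs(m)
  expect_length(blobs, 2)
  expect_equal(vapply(blobs, function(b) b$area_px, 0), c(40, 9))
  expect_equal(sum(vapply(blobs, function(b) b$area_px, 0)), sum(m))
  expect_gt(blobs[[1]]$elongation, blobs[[2]]$elongation)
  expect_equal(blobs[[2]]$elongation, 1, tolerance = 1e-9)
  expect_equal(blobs[[1]]$solidity, 1, tolerance = 1e-9)

  # diagonal touching pixels are one 8-connected component
  d <- matrix(0L, 4, 4); d[1, 1] <- 1L; d[2, 2] <- 1L
  expect_length(find_blobs(d), 1)

  # partition property on a random mask
  set.seed(33)
  rm_ <- matrix(rbinom(400, 1, 0.3), 20, 20)
  bl <- find_blobs(rm_)
  expect_equal(sum(vapply(bl, function(b) b$area_px, 0)), sum(rm_))
})

test_that("select_fish_blob applies size/shape gates with a total-order tie-break", {
  expect_null(select_fish_blob(list(), selection_criteria(), 1000))

  m <- matrix(0L, 40, 80)
  m[10:13, 10:49] <- 1L    # elongated 40 x 4 blob
  m[30, 60] <- 1L          # 1-px speck
  blobs <- find_blobs(m)
  crit <- selection_criteria(min_area_frac = 0.01, max_area_frac = 0.5,
                             min_elongation = 2.5, min_solidity = 0.3,
                             max_solidity = 1)
  sel <- select_fish_blob(blobs, crit, roi_area = 40 * 80)
  expect_equal(sel$area_px, 160)
  expect_equal(attr(sel, "n_candidates"), 1L)

  # two qualifying blobs: larger wins; equal areas: larger elongation wins
  m2 <- matrix(0L, 60, 120)
  m2[5:8, 5:64] <- 1L      # area 240
  m2[40:43, 5:44] <- 1L    # area 160
  s2 <- select_fish_blob(find_blobs(m2), crit, roi_area = 60 * 120)
  expect_equal(s2$area_px, 240)
  expect_equal(attr(s2, "n_candidates"), 2L)

  m3 <- matrix(0L, 60, 120)
  m3[5:8, 11:50] <- 1L                 # 40 x 4
  m3[31:32, 31:110] <- 1L              # 80 x 2, same area, more elongated
  s3 <- select_fish_blob(find_blobs(m3), crit, roi_area = 60 * 120)
  expect_equal(unname(s3$bbox$y0), 30)  # the more elongated one
})

test_that("motion clipping shrinks to the fish and falls back on static scenes", {
  # static scene: full roi returned for every frame
  static <- replicate(6, matrix(100, 30, 40), simplify = FALSE)
  r <- roi(0, 0, 40, 30)
  clips <- motion_clip(static, r, bg_frames = 4)
  expect_true(all(vapply(clips, function(cl) identical(cl, r), TRUE)))

  # synthetic fish: clip box contains the ground-truth midline, and is
  # always a subset of the roi
  cfg <- tiny_cfg(duration_s = 0.08)
  v <- generate_video(cfg)
  r2 <- roi(0, 0, cfg$frame_size[1], cfg$frame_size[2])
  clips2 <- motion_clip(v$frames, r2, bg_frames = 10)
  for (k in seq_along(clips2)) {
    cl <- clips2[[k]]
    expect_true(cl$x0 >= 0 && cl$y0 >= 0 &&
                  cl$x0 + cl$width <= r2$width &&
                  cl$y0 + cl$height <= r2$height)
    ml <- v$midlines[[k]]
    expect_true(all(ml[, 1] >= cl$x0 & ml[, 1] < cl$x0 + cl$width &
                      ml[, 2] >= cl$y0 & ml[, 2] < cl$y0 + cl$height))
  }

  # single frame: full roi with a warning flag
  one <- motion_clip(static[1], r)
  expect_identical(one[[1]], r)
  expect_match(attr(one, "warning"), "single frame")
})
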