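test_that("joint angles reproduce closed-form cases and rigid invariance", {
  # collinear points -> all zeros
  col4 <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_equal(unname(joint_angles(col4)), c(0, 0, 0))

  # right-angle construction: |beta| = 90, gamma = 0, |alpha| = 90
  pts <- cbind(c(0, 1, 1, 1), c(0, 0, 1, 2))
  ang <- joint_angles(pts)
  expect_equal(abs(ang[["beta_deg"]]), 90)
  expect_equal(ang[["gamma_deg"]], 0)
  expect_equal(abs(ang[["alpha_deg"]]), 90)
  expect_equal(ang[["alpha_deg"]], ang[["beta_deg"]])  # same turning sense

  # rigid motions leave all three angles unchanged (100 random transforms)
  set.seed(7)
  base <- cbind(runif(4, 0, 10), runif(4, 0, 10))
  ref <- joint_angles(base)
  for (i in 1:100) {
    moved <- rigid_transform(base, runif(1, 0, 2 * pi),
                             runif(1, -50, 50), runif(1, -50, 50))
    expect_equal(joint_angles(moved), ref, tolerance = 1e-9)
  }

  expect_error(joint_angles(cbind(c(0, 0, 1, 2), c(0, 0, 1, 2))),
               class = "gaitkin_coincident_points")
})

test_that("tail amplitude is the D-to-head-line distance, rigid invariant", {
  # D on the AB line -> 0
  expect_equal(tail_amplitude(cbind(c(0, 1, 2, 3), c(0, 0, 1, 0))), 0)

  # A=(0,0), B=(1,0), D=(5,3) -> 3
  pts <- cbind(c(0, 1, 3, 5), c(0, 0, 2, 3))
  expect_equal(tail_amplitude(pts), 3)

  set.seed(8)
  for (i in 1:50) {
    moved <- rigid_transform(pts, runif(1, 0, 2 * pi),
                             runif(1, -30, 30), runif(1, -30, 30))
    expect_equal(tail_amplitude(moved), 3, tolerance = 1e-9)
  }

  expect_error(tail_amplitude(cbind(c(1, 1, 2, 3), c(2, 2, 3, 4))),
               class = "gaitkin_coincident_points")
})

test_that("half cycles are the intervals between consecutive zero crossings", {
  fps <- 1000
  t <- (0:999) / fps
  s10 <- 40 * sin(2 * pi * 10 * t + 1)
  hc <- find_half_cycles(s10, fps)
  # 20 crossings in the fragment bound 19 complete inter-crossing intervals
  expect_length(attr(hc, "crossings"), 20)
  expect_equal(nrow(hc), 19)
  expect_true(all(abs((hc[, 2] - hc[, 1]) - 50) <= 2))  # ~50-frame halves

  # constant signal -> no half cycles
  expect_equal(nrow(find_half_cycles(rep(3, 400), fps)), 0)

  # 7.5 Hz over 2 s: 30 crossings -> 29 intervals
  t2 <- (0:1999) / fps
  hc2 <- find_half_cycles(25 * sin(2 * pi * 7.5 * t2 + 1), fps)
  expect_length(attr(hc2, "crossings"), 30)
  expect_equal(nrow(hc2), 29)
})

test_that("cycle-counting frequency matches truth and the Fourier oracle", {
  fps <- 1000
  t <- (0:999) / fps
  clean <- 30 * sin(2 * pi * 10 * t + 0.4)
  f_clean <- mean_frequency(clean, fps)
  expect_equal(f_clean, 10, tolerance = 0.1)

  # 10% additive noise, seeded
  set.seed(17)
  noisy <- clean + rnorm(length(clean), sd = 3)
  expect_equal(mean_frequency(noisy, fps), 10, tolerance = 0.3)

  # agreement with the Fourier peak within one frequency bin (1 Hz here)
  expect_lt(abs(f_clean - ref_fourier_peak_hz(clean, fps)), 1)

  # too-short fragment: undefined, flagged
  short <- 30 * sin(2 * pi * 10 * t[1:120])
  f_short <- mean_frequency(short, fps)
  expect_true(is.na(f_short))
  expect_match(attr(f_short, "reason"), "cycles")
})

test_that("half-cycle curvature recovers the (2/pi) * peak closed form", {
  fps <- 1000
  t <- (0:1999) / fps
  for (P in c(12, 35)) {
    s <- P * sin(2 * pi * 10 * t + 0.2)
    hc <- find_half_cycles(s, fps)
    expect_equal(half_cycle_curvature(s, hc), 2 / pi * P,
                 tolerance = 0.01 * 2 / pi * P)
  }

  # zero signal with artificial intervals -> 0; doubling doubles (homogeneity)
  iv <- cbind(start = c(1, 51), end = c(51, 101))
  expect_equal(half_cycle_curvature(rep(0, 100), iv), 0)
  s <- sin(2 * pi * 10 * t[1:100])
  expect_equal(half_cycle_curvature(2 * s, iv), 2 * half_cycle_curvature(s, iv))

  r <- half_cycle_curvature(s, matrix(integer(0), 0, 2))
  expect_true(is.na(r))
})

test_that("summarize_gait recovers ground-truth kinematics from a synthetic trace", {
  cfg <- tiny_cfg(duration_s = 0.5, fps = 1000,
                  frame_size = c(128, 64))
  v <- generate_video(cfg)
  gt <- v$ground_truth
  tr <- gait_trace(data.frame(frame_index = gt$frame_index, valid = TRUE,
                              invalid_reason = "",
                              alpha_deg = gt$alpha_deg, beta_deg = gt$beta_deg,
                              gamma_deg = gt$gamma_deg,
                              amplitude_px = gt$amplitude_px),
                   fps = cfg$fps, body_length_px = cfg$body_length_px)
  s <- summarize_gait(tr)
  expect_equal(unname(s$freq_hz), rep(10, 3), tolerance = 0.02)
  expect_equal(s$invalid_fraction, 0)
  expect_true(all(s$n_cycles >= 4))

  # straight-swimming fish: zero amplitude summary
  cfg0 <- tiny_cfg(amplitude_envelope = function(s) rep(0, length(s)),
                   duration_s = 0.2)
  gt0 <- generate_video(cfg0)$ground_truth
  tr0 <- gait_trace(data.frame(frame_index = gt0$frame_index, valid = TRUE,
                               invalid_reason = "",
                               alpha_deg = gt0$alpha_deg,
                               beta_deg = gt0$beta_deg,
                               gamma_deg = gt0$gamma_deg,
                               amplitude_px = gt0$amplitude_px),
                    fps = cfg0$fps, body_length_px = cfg0$body_length_px)
  s0 <- summarize_gait(tr0)
  expect_equal(s0$amplitude_mean_px, 0)
  expect_equal(s0$amplitude_mean_bl, 0)
})

test_that("summaries are invariant under time reversal of the trace", {
  cfg <- tiny_cfg(duration_s = 0.5, fps = 1000)
  gt <- generate_video(cfg)$ground_truth
  mk <- function(df) gait_trace(df, fps = cfg$fps,
                                body_length_px = cfg$body_length_px)
  fwd <- data.frame(frame_index = gt$frame_index, valid = TRUE,
                    invalid_reason = "", alpha_deg = gt$alpha_deg,
                    beta_deg = gt$beta_deg, gamma_deg = gt$gamma_deg,
                    amplitude_px = gt$amplitude_px)
  rev_ <- fwd[nrow(fwd):1, ]
  rev_$frame_index <- fwd$frame_index
  s1 <- summarize_gait(mk(fwd))
  s2 <- summarize_gait(mk(rev_))
  expect_equal(s1$freq_hz, s2$freq_hz, tolerance = 0.05)
  expect_equal(s1$half_cycle_curvature_deg, s2$half_cycle_curvature_deg,
               tolerance = 0.15)
})

test_that("invalid-frame gaps are bridged up to max_gap, then split the trace", {
  fps <- 1000
  t <- (0:999) / fps
  alpha <- 20 * sin(2 * pi * 10 * t + 0.5)
  df <- data.frame(frame_index = 0:999, valid = TRUE, invalid_reason = "",
                   alpha_deg = alpha, beta_deg = alpha, gamma_deg = alpha,
                   amplitude_px = abs(alpha))
  # a short dropout (10 frames) must not change the frequency materially
  df_gap <- df
  df_gap$valid[301:310] <- FALSE
  df_gap[301:310, c("alpha_deg", "beta_deg", "gamma_deg", "amplitude_px")] <- NA
  s_gap <- summarize_gait(gait_trace(df_gap, fps, 100))
  expect_equal(unname(s_gap$freq_hz), rep(10, 3), tolerance = 0.2)
  expect_equal(s_gap$invalid_fraction, 0.01)

  # a long dropout (100 frames) splits the trace; cycles still pool to ~10 Hz
  df_long <- df
  df_long$valid[401:500] <- FALSE
  df_long[401:500, c("alpha_deg", "beta_deg", "gamma_deg", "amplitude_px")] <- NA
  s_long <- summarize_gait(gait_trace(df_long, fps, 100))
  expect_equal(unname(s_long$freq_hz), rep(10, 3), tolerance = 0.2)
})
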