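#' Synthetic undulating-fish model configuration
#'
#' Describes a ground-truthed synthetic video of a single dark fish
#' silhouette swimming on a lighter background. The midline follows a
#' single sinusoidal traveling bending wave, the canonical kinematic model
#' of carangiform swimming: the lateral displacement at normalized arc
#' position `s` (0 = snout, 1 = end of the caudal peduncle) and time `t` is
#'
#'   `y(s, t) = A(s) * sin(2*pi*f*t - 2*pi*s / wavelength_bl)`
#'
#' with `A(s)` the amplitude envelope (default: linear ramp from
#' `amp_head_px` to `amp_tail_px`) and `f = wave_frequency_hz`. The
#' displaced curve is re-scaled axially so its arc length always equals
#' `body_length_px`, keeping the body length (the BL unit) well defined
#' under bending.
#'
#' @param body_length_px Body (standard) length in pixels.
#' @param n_midline_samples Number of midline sample points (>= 16).
#' @param wave_frequency_hz Tail-beat frequency f in Hz.
#' @param wavelength_bl Body wavelength in body lengths.
#' @param amp_head_px,amp_tail_px Endpoints of the default linear
#'   amplitude envelope, in pixels.
#' @param amplitude_envelope Function of `s` in \[0, 1\] giving lateral
#'   amplitude in pixels; overrides the linear ramp if supplied.
#' @param thickness_profile Function of `s` giving the body half-width in
#'   pixels; the default is wide near the head and tapers to a thin caudal
#'   peduncle.
#' @param frame_size `c(width, height)` in pixels.
#' @param fps Frames per second.
#' @param duration_s Video duration in seconds.
#' @param background_intensity,fish_intensity Gray levels in \[0, 255\];
#'   the fish must be darker than the background (silhouette imaging).
#' @param noise_sigma Standard deviation of i.i.d. additive Gaussian pixel
#'   noise (0 = noiseless).
#' @param seed Integer seed making rendering a pure function of
#'   `(cfg, frame_index)`.
#' @return An object of class `"fish_model_config"`.
#' @export
fish_model_config <- function(body_length_px = 200, n_midline_samples = 100,
                              wave_frequency_hz = 10, wavelength_bl = 0.95,
                              amp_head_px = 2, amp_tail_px = 15,
                              amplitude_envelope = NULL,
                              thickness_profile = NULL,
                              frame_size = c(512, 160), fps = 1000,
                              duration_s = 1,
                              background_intensity = 200,
                              fish_intensity = 60,
                              noise_sigma = 0, seed = 1L) {
  if (body_length_px <= 0 || wave_frequency_hz <= 0 || wavelength_bl <= 0 ||
      fps <= 0 || duration_s <= 0 || noise_sigma < 0)
    stop_gaitkin("model scalars must be positive (noise_sigma >= 0)",
                 "gaitkin_bad_input")
  if (n_midline_samples < 16)
    stop_gaitkin("n_midline_samples must be >= 16", "gaitkin_bad_input")
  if (fish_intensity >= background_intensity)
    stop_gaitkin("fish must be darker than the background", "gaitkin_bad_input")
  env <- amplitude_envelope %||%
    default_amplitude_envelope(amp_head_px, amp_tail_px)
  thick <- thickness_profile %||% default_thickness_profile(body_length_px)
  s <- seq(0, 1, length.out = 257)
  if (any(env(s) < 0))
    stop_gaitkin("amplitude_envelope must be >= 0", "gaitkin_bad_input")
  max_th <- max(thick(s))
  max_amp <- max(env(s))
  if (body_length_px + 2 * max_th > frame_size[1] ||
      2 * (max_amp + max_th) + 2 > frame_size[2])
    stop_gaitkin("fish does not fit inside frame_size", "gaitkin_bad_input")
  structure(list(body_length_px = body_length_px,
                 n_midline_samples = as.integer(n_midline_samples),
                 wave_frequency_hz = wave_frequency_hz,
                 wavelength_bl = wavelength_bl,
                 amp_head_px = amp_head_px, amp_tail_px = amp_tail_px,
                 amplitude_envelope = env, thickness_profile = thick,
                 frame_size = as.integer(frame_size), fps = fps,
                 duration_s = duration_s,
                 background_intensity = background_intensity,
                 fish_intensity = fish_intensity,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "fish_model_config")
}

#' @rdname fish_model_config
#' @export
default_amplitude_envelope <- function(amp_head_px, amp_tail_px) {
  force(amp_head_px); force(amp_tail_px)
  function(s) amp_head_px + (amp_tail_px - amp_head_px) * s
}

#' @rdname fish_model_config
#' @param h_max Maximum half-width in pixels (default 5.5% of body length).
#' @param h_min Minimum half-width floor in pixels.
#' @export
default_thickness_profile <- function(body_length_px, h_max = 0.055 * body_length_px,
                                      h_min = 1.5) {
  force(h_max); force(h_min)
  # rounded snout (ellipse cap for s < 0.25), long taper to the peduncle
  function(s) {
    w <- ifelse(s < 0.25, 0.25, 0.78)
    pmax(h_min, h_max * sqrt(pmax(0, 1 - ((s - 0.25) / w)^2)))
  }
}

#' Midline of the model fish at a given time
#'
#' Samples the traveling-wave midline at `n_midline_samples` arc positions,
#' re-scales the bent curve axially so its total arc length equals
#' `body_length_px`, and places it rigidly, centered in the frame with the
#' head at the smaller-x end. The lateral displacement of each sample is
#' exactly `amplitude_envelope(s) * sin(2*pi*f*t - 2*pi*s/wavelength_bl)`
#' (axial re-scaling does not touch the lateral coordinate).
#'
#' @param cfg A [fish_model_config()].
#' @param t Time in seconds (>= 0).
#' @return An `n x 2` matrix of (x, y) midline points, head to tail, in
#'   0-based pixel-center coordinates.
#' @export
midline_at_time <- function(cfg, t) {
  if (t < 0) stop_gaitkin("t must be >= 0", "gaitkin_bad_input")
  n <- cfg$n_midline_samples
  s <- seq(0, 1, length.out = n)
  L <- cfg$body_length_px
  y <- cfg$amplitude_envelope(s) *
    sin(2 * pi * cfg$wave_frequency_hz * t - 2 * pi * s / cfg$wavelength_bl)
  arclen_at <- function(cc) sum(sqrt((cc * L * diff(s))^2 + diff(y)^2))
  c_scale <- if (max(abs(y)) < 1e-12 || arclen_at(1) <= L) 1 else
    stats::uniroot(function(cc) arclen_at(cc) - L,
                   lower = 1e-6, upper = 1, tol = 1e-10)$root
  xc <- (cfg$frame_size[1] - 1) / 2
  yc <- (cfg$frame_size[2] - 1) / 2
  x <- xc + c_scale * L * (s - 0.5)
  cbind(x = x, y = yc + y)
}

#' Render one frame of the synthetic video
#'
#' Pixels whose center lies within `thickness_profile(s)` of the nearest
#' midline point (at arc position `s`) receive `fish_intensity`; all others
#' `background_intensity`. When `noise_sigma > 0`, i.i.d. Gaussian noise is
#' added and the result clipped to \[0, 255\]; the noise stream is derived
#' from `(cfg$seed, frame_index)` so rendering is bit-reproducible.
#'
#' @param midline `n x 2` midline point matrix, as from [midline_at_time()].
#' @param cfg A [fish_model_config()].
#' @param frame_index Frame number (>= 0), used only to seed the noise.
#' @return A `height x width` numeric matrix with values in \[0, 255\].
#' @export
render_frame <- function(midline, cfg, frame_index = 0L) {
  w <- cfg$frame_size[1]; h <- cfg$frame_size[2]
  n <- nrow(midline)
  s <- seq(0, 1, length.out = n)
  max_th <- max(cfg$thickness_profile(s))
  if (any(midline[, 1] < max_th) || any(midline[, 1] > w - 1 - max_th) ||
      any(midline[, 2] < max_th) || any(midline[, 2] > h - 1 - max_th))
    stop_gaitkin("midline (dilated by thickness) out of frame bounds",
                 "gaitkin_bad_input")
  frame <- matrix(cfg$background_intensity, nrow = h, ncol = w)

  # candidate pixels: bounding box of the midline dilated by max thickness
  pad <- ceiling(max_th) + 1L
  cmin <- max(1L, floor(min(midline[, 1])) + 1L - pad)
  cmax <- min(w, ceiling(max(midline[, 1])) + 1L + pad)
  rmin <- max(1L, floor(min(midline[, 2])) + 1L - pad)
  rmax <- min(h, ceiling(max(midline[, 2])) + 1L + pad)
  px <- as.vector(outer(rep(1, rmax - rmin + 1L), (cmin:cmax) - 1))
  py <- as.vector(outer((rmin:rmax) - 1, rep(1, cmax - cmin + 1L)))

  best_d2 <- rep(Inf, length(px))
  best_s <- rep(0, length(px))
  for (j in seq_len(n - 1L)) {
    x1 <- midline[j, 1]; y1 <- midline[j, 2]
    vx <- midline[j + 1L, 1] - x1; vy <- midline[j + 1L, 2] - y1
    l2 <- vx * vx + vy * vy
    tt <- if (l2 > 0) clamp(((px - x1) * vx + (py - y1) * vy) / l2, 0, 1) else 0
    dx <- px - (x1 + tt * vx); dy <- py - (y1 + tt * vy)
    d2 <- dx * dx + dy * dy
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_s[upd] <- s[j] + tt[upd] * (s[j + 1L] - s[j])
  }
  inside <- best_d2 <= cfg$thickness_profile(best_s)^2
  sub <- matrix(cfg$background_intensity, nrow = rmax - rmin + 1L,
                ncol = cmax - cmin + 1L)
  sub[inside] <- cfg$fish_intensity
  frame[rmin:rmax, cmin:cmax] <- sub

  if (cfg$noise_sigma > 0) {
    frame <- with_private_seed(cfg$seed * 1009L + as.integer(frame_index), {
      clamp(frame + stats::rnorm(length(frame), sd = cfg$noise_sigma), 0, 255)
    })
  }
  frame
}

#' Generate a ground-truthed synthetic video
#'
#' Renders `round(duration_s * fps)` frames sampled at `t = k / fps` and
#' tabulates, per frame, the true midline, the four equidistant points
#' A--D, the inter-segment angles and the tail-beat amplitude. Ground
#' truth is computed with the very same geometry functions
#' ([equidistant_points()], [joint_angles()], [tail_amplitude()]) the
#' analysis pipeline uses, so there is no second definition to drift.
#'
#' @param cfg A [fish_model_config()].
#' @return A list of class `"synth_video"` with elements `frames` (list of
#'   matrices), `ground_truth` (data frame: `frame_index`, `t_s`,
#'   `Ax`..`Dy`, `alpha_deg`, `beta_deg`, `gamma_deg`, `amplitude_px`),
#'   `midlines` (list of point matrices) and `config`.
#' @export
generate_video <- function(cfg) {
  n_frames <- round(cfg$duration_s * cfg$fps)
  frames <- vector("list", n_frames)
  midlines <- vector("list", n_frames)
  gt <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    t <- (k - 1) / cfg$fps
    ml <- midline_at_time(cfg, t)
    frames[[k]] <- render_frame(ml, cfg, frame_index = k - 1L)
    midlines[[k]] <- ml
    pts <- equidistant_points(ml, 4L)
    ang <- joint_angles(pts)
    gt[[k]] <- data.frame(frame_index = k - 1L, t_s = t,
                          Ax = pts[1, 1], Ay = pts[1, 2],
                          Bx = pts[2, 1], By = pts[2, 2],
                          Cx = pts[3, 1], Cy = pts[3, 2],
                          Dx = pts[4, 1], Dy = pts[4, 2],
                          alpha_deg = ang[["alpha_deg"]],
                          beta_deg = ang[["beta_deg"]],
                          gamma_deg = ang[["gamma_deg"]],
                          amplitude_px = tail_amplitude(pts))
  }
  structure(list(frames = frames, ground_truth = do.call(rbind, gt),
                 midlines = midlines, config = cfg),
            class = "synth_video")
}

#' @export
print.synth_video <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<synth_video: %d frames %dx%d px, %g fps, f = %g Hz, tail amp = %g px>\n",
              length(x$frames), cfg$frame_size[1], cfg$frame_size[2],
              cfg$fps, cfg$wave_frequency_hz, cfg$amp_tail_px))
  invisible(x)
}

#' Corrupt selected frames of a frame stack
#'
#' Injects controlled defects to exercise the per-frame validity checks:
#' `"blank"` replaces the frame by its uniform background level (no blob
#' remains), `"split_blob"` draws a background-colored vertical band
#' through the body so the silhouette falls apart into two components,
#' `"speckle"` sprinkles small foreground-colored specks (structured
#' clutter). Untouched frames are returned bit-identical.
#'
#' @param frames List of frame matrices (or a `"synth_video"`).
#' @param indices Integer vector of 0-based frame indices to corrupt.
#' @param mode One of `"blank"`, `"split_blob"`, `"speckle"`.
#' @param seed Seed for speckle placement.
#' @param n_specks,speck_size Speckle count and square speck side (px).
#' @return The frame list with the selected frames corrupted.
#' @export
corrupt_frames <- function(frames, indices,
                           mode = c("blank", "split_blob", "speckle"),
                           seed = 0L, n_specks = 150L, speck_size = 2L) {
  if (inherits(frames, "synth_video")) frames <- frames$frames
  mode <- match.arg(mode)
  n <- length(frames)
  indices <- as.integer(indices)
  if (length(indices) && (min(indices) < 0L || max(indices) >= n))
    stop_gaitkin("corruption indices out of range", "gaitkin_bad_input")
  for (i in indices) {
    f <- frames[[i + 1L]]
    bg <- stats::median(f)
    if (mode == "blank") {
      f[] <- bg
    } else if (mode == "split_blob") {
      # cut at the center of the dark silhouette's horizontal extent so
      # the two remaining components have comparable size
      dark_cols <- which(apply(f, 2, min) < (max(f) + min(f)) / 2)
      cc <- if (length(dark_cols)) round(mean(range(dark_cols)))
            else ncol(f) %/% 2L
      band <- max(1L, cc - 4L):min(ncol(f), cc + 4L)
      f[, band] <- bg
    } else { # speckle
      dark <- min(f)
      f <- with_private_seed(seed * 2003L + i, {
        for (k in seq_len(n_specks)) {
          r <- sample.int(nrow(f) - speck_size + 1L, 1L)
          c <- sample.int(ncol(f) - speck_size + 1L, 1L)
          f[r:(r + speck_size - 1L), c:(c + speck_size - 1L)] <- dark
        }
        f
      })
    }
    frames[[i + 1L]] <- f
  }
  frames
}
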