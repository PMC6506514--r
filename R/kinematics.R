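#' Inter-segment angles of the four-point body parameterization
#'
#' The dorsal is approximated by three straight segments AB (head), BC
#' (trunk) and CD (tail). With direction vectors `u_head = B - A`,
#' `u_trunk = C - B`, `u_tail = D - C`, the body curvature is measured by
#' three signed turning angles in degrees: the head-trunk angle
#' `beta = angle(u_head -> u_trunk)`, the trunk-tail angle
#' `gamma = angle(u_trunk -> u_tail)` and the head-tail angle
#' `alpha = angle(u_head -> u_tail)`. Sign convention: positive =
#' counterclockwise turning in image coordinates (x right, y down), i.e.
#' positive `atan2(cross, dot)` with `cross = ux*vy - uy*vx`; only
#' absolute angles enter the downstream summaries. A straight body gives
#' all zeros; angles are invariant under rigid motions of the four points.
#'
#' @param points `4 x 2` matrix with rows A, B, C, D (as from
#'   [equidistant_points()]); the four points must be pairwise distinct.
#' @return Named numeric vector `c(alpha_deg, beta_deg, gamma_deg)` in
#'   (-180, 180].
#' @export
joint_angles <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 4L)
    stop_gaitkin("need exactly 4 points (A, B, C, D)", "gaitkin_bad_input")
  dmat <- as.matrix(stats::dist(points))
  if (any(dmat[upper.tri(dmat)] < 1e-12))
    stop_gaitkin("coincident points", "gaitkin_coincident_points")
  u_head <- points[2, ] - points[1, ]
  u_trunk <- points[3, ] - points[2, ]
  u_tail <- points[4, ] - points[3, ]
  turn <- function(u, v)
    unname(atan2(u[1] * v[2] - u[2] * v[1], u[1] * v[1] + u[2] * v[2])) * 180 / pi
  c(alpha_deg = turn(u_head, u_tail),
    beta_deg = turn(u_head, u_trunk),
    gamma_deg = turn(u_trunk, u_tail))
}

#' Per-frame tail-beat amplitude
#'
#' The distance between the end of the caudal peduncle (point D) and the
#' infinite line including the head segment AB, in pixels. Invariant under
#' rigid motions; zero when D lies on the head line.
#'
#' @param points `4 x 2` matrix with rows A, B, C, D (`A != B`).
#' @return Non-negative scalar distance in pixels.
#' @export
tail_amplitude <- function(points) {
  points <- as.matrix(points)
  a <- points[1, ]; b <- points[2, ]; d <- points[4, ]
  ab <- b - a
  nrm <- sqrt(sum(ab^2))
  if (nrm < 1e-12) stop_gaitkin("A and B coincide", "gaitkin_coincident_points")
  unname(abs(ab[1] * (d[2] - a[2]) - ab[2] * (d[1] - a[1])) / nrm)
}

# Mean-subtract and low-pass filter a signal; returns the filtered signal.
# smooth_hz >= Nyquist or very short signals skip the filter.
smooth_signal <- function(x, fps, smooth_hz) {
  x <- x - mean(x)
  if (is.null(smooth_hz) || smooth_hz <= 0 || smooth_hz >= fps / 2 ||
      length(x) < 30L)
    return(x)
  bf <- signal::butter(4, smooth_hz / (fps / 2))
  as.numeric(signal::filtfilt(bf, x))
}

# Fractional zero-crossing positions (1-based frame units) of a signal.
zero_crossing_positions <- function(s) {
  if (all(s == 0)) return(numeric(0))
  # zeros adopt the sign of the previous nonzero sample (leading zeros the next)
  sg <- sign(s)
  nz <- sg != 0
  if (!any(nz)) return(numeric(0))
  filled <- sg
  last <- sg[which(nz)[1]]
  for (i in seq_along(filled)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  i <- which(filled[-length(filled)] * filled[-1] < 0)
  if (length(i) == 0L) return(numeric(0))
  i + s[i] / (s[i] - s[i + 1L])
}

#' Half cycles of a bending-angle signal
#'
#' A half cycle of bending is the interval between two consecutive zero
#' crossings of the mean-subtracted, low-pass-filtered signed angle
#' signal. Crossing positions are located with linear interpolation and
#' rounded to frame indices; intervals shorter than 3 frames are merged
#' into their neighbor. With `m` crossings the signal yields `m - 1` half
#' cycles; fewer than 3 crossings yield none (and downstream summary
#' fields are flagged undefined).
#'
#' @param signal Numeric vector of signed angles (degrees) per frame.
#' @param fps Frame rate in Hz.
#' @param smooth_hz Low-pass cutoff in Hz (default 25, far above any
#'   zebrafish tail-beat frequency yet killing pixel jitter); `0` or
#'   `>= fps/2` disables filtering.
#' @return A two-column integer matrix (`start`, `end`) of half-open
#'   1-based frame intervals `[start, end)`; zero rows if fewer than 3
#'   crossings. Attribute `"crossings"` holds the fractional crossing
#'   positions (1-based frame units).
#' @export
find_half_cycles <- function(signal, fps, smooth_hz = 25) {
  s <- smooth_signal(signal, fps, smooth_hz)
  cr <- zero_crossing_positions(s)
  empty <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("start", "end")))
  if (length(cr) < 3L) {
    attr(empty, "crossings") <- cr
    return(empty)
  }
  b <- round(cr)
  b <- pmin(pmax(b, 1L), length(signal))
  iv <- cbind(start = b[-length(b)], end = b[-1])
  iv <- iv[iv[, 2] > iv[, 1], , drop = FALSE]
  # merge intervals shorter than 3 frames into the previous (or next)
  i <- 1L
  while (i <= nrow(iv)) {
    if (iv[i, 2] - iv[i, 1] < 3L && nrow(iv) > 1L) {
      if (i > 1L) {
        iv[i - 1L, 2] <- iv[i, 2]
        iv <- iv[-i, , drop = FALSE]
      } else {
        iv[2L, 1] <- iv[1L, 1]
        iv <- iv[-1L, , drop = FALSE]
      }
    } else i <- i + 1L
  }
  attr(iv, "crossings") <- cr
  iv
}

#' Mean tail-beat frequency by cycle counting
#'
#' Counts full cycles (two consecutive half cycles) between zero
#' crossings of the filtered signal and divides by the time spanned from
#' the first to the last used crossing, using data from all the cycles of
#' the fragment. Requires at least 2 full cycles, otherwise `NA` is
#' returned with attribute `"reason"`.
#'
#' @inheritParams find_half_cycles
#' @return Frequency in Hz (scalar), or `NA`.
#' @export
mean_frequency <- function(signal, fps, smooth_hz = 25) {
  hc <- find_half_cycles(signal, fps, smooth_hz)
  cr <- attr(hc, "crossings")
  n_full <- floor((length(cr) - 1) / 2)
  if (n_full < 2) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 2 full cycles"
    return(out)
  }
  span_s <- (cr[2 * n_full + 1] - cr[1]) / fps
  n_full / span_s
}

#' Average half-cycle curvature
#'
#' For each half cycle, the time average of the absolute signed angle over
#' its frames; the returned value is the mean across half cycles. For a
#' sinusoidal angle of peak P this converges to `(2/pi) * P`.
#'
#' @param signal Numeric vector of signed angles (degrees).
#' @param half_cycles Interval matrix from [find_half_cycles()].
#' @return Mean absolute angle in degrees, or `NA` if no half cycles.
#' @export
half_cycle_curvature <- function(signal, half_cycles) {
  if (is.null(half_cycles) || nrow(half_cycles) == 0L) {
    out <- NA_real_
    attr(out, "reason") <- "no half cycles"
    return(out)
  }
  per <- apply(half_cycles, 1, function(iv)
    mean(abs(signal[iv[1]:(iv[2] - 1L)])))
  mean(per)
}

#' Assemble a per-frame kinematic trace
#'
#' @param frames Data frame with columns `frame_index`, `valid`,
#'   `invalid_reason`, `alpha_deg`, `beta_deg`, `gamma_deg`,
#'   `amplitude_px` (invalid frames carry `NA` kinematics).
#' @param fps Frame rate in Hz.
#' @param body_length_px Body length in pixels used for BL normalization.
#' @return An object of class `"gait_trace"`; `amplitude_bl` is derived
#'   as `amplitude_px / body_length_px`.
#' @export
gait_trace <- function(frames, fps, body_length_px) {
  if (fps <= 0) stop_gaitkin("fps must be > 0", "gaitkin_bad_input")
  if (is.unsorted(frames$frame_index, strictly = TRUE))
    stop_gaitkin("frame_index must be strictly increasing", "gaitkin_bad_input")
  frames$amplitude_bl <- frames$amplitude_px / body_length_px
  structure(list(fps = fps, body_length_px = body_length_px, frames = frames),
            class = "gait_trace")
}

#' @export
print.gait_trace <- function(x, ...) {
  cat(sprintf("<gait_trace: %d frames at %g fps, body length %.1f px, %.1f%% invalid>\n",
              nrow(x$frames), x$fps, x$body_length_px,
              100 * mean(!x$frames$valid)))
  invisible(x)
}

# Split a signal with NA gaps into index segments, bridging gaps <=
# max_gap frames by linear interpolation. Returns list of (start, values).
segment_signal <- function(x, max_gap) {
  filled <- zoo::na.approx(x, na.rm = FALSE, maxgap = max_gap)
  ok <- !is.na(filled)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) list(start = starts[i],
                               values = filled[starts[i]:ends[i]]))
}

#' Summarize a gait trace
#'
#' Computes, for each angle signal (alpha, beta, gamma): the half cycles,
#' the mean tail-beat frequency (total full cycles over total spanned
#' time, pooled across trace segments) and the average half-cycle
#' curvature. The tail-beat amplitude endpoint is the mean over half
#' cycles of the gamma signal of the per-half-cycle peak amplitude (the
#' conventional "peak excursion per beat"); if no half cycles exist (e.g.
#' straight swimming) it falls back to the mean per-frame amplitude.
#' Invalid-frame gaps of at most `max_gap` frames are bridged by linear
#' interpolation; longer gaps split the trace into segments whose cycles
#' are counted separately and pooled.
#'
#' @param trace A [gait_trace()].
#' @param smooth_hz Low-pass cutoff for half-cycle detection (Hz).
#' @param max_gap Longest invalid gap (frames) bridged by interpolation.
#' @return An object of class `"gait_summary"` with fields `freq_hz`,
#'   `half_cycle_curvature_deg`, `curvature_peak_deg` (per-half-cycle peak
#'   |angle|, an optional companion statistic), `amplitude_mean_bl`,
#'   `amplitude_mean_px`, `n_cycles` (each per angle where applicable),
#'   `invalid_fraction` and `n_frames`.
#' @export
summarize_gait <- function(trace, smooth_hz = 25, max_gap = 20) {
  fr <- trace$frames
  if (!any(fr$valid)) stop_gaitkin("no valid frames", "gaitkin_bad_input")
  fps <- trace$fps
  angles <- c(alpha = "alpha_deg", beta = "beta_deg", gamma = "gamma_deg")
  freq <- curv <- curv_peak <- ncyc <- stats::setNames(rep(NA_real_, 3), names(angles))
  gamma_cycles <- list()
  for (a in names(angles)) {
    x <- fr[[angles[[a]]]]
    x[!fr$valid] <- NA
    segs <- segment_signal(x, max_gap)
    tot_cycles <- 0; tot_span <- 0
    per_means <- numeric(0); per_peaks <- numeric(0)
    for (sg in segs) {
      hc <- find_half_cycles(sg$values, fps, smooth_hz)
      cr <- attr(hc, "crossings")
      nf <- floor((length(cr) - 1) / 2)
      if (nf >= 1) {
        tot_cycles <- tot_cycles + nf
        tot_span <- tot_span + (cr[2 * nf + 1] - cr[1]) / fps
      }
      if (nrow(hc) > 0) {
        per_means <- c(per_means, apply(hc, 1, function(iv)
          mean(abs(sg$values[iv[1]:(iv[2] - 1L)]))))
        per_peaks <- c(per_peaks, apply(hc, 1, function(iv)
          max(abs(sg$values[iv[1]:(iv[2] - 1L)]))))
        if (a == "gamma") {
          gamma_cycles <- c(gamma_cycles, lapply(seq_len(nrow(hc)), function(i)
            c(sg$start + hc[i, 1] - 1L, sg$start + hc[i, 2] - 1L)))
        }
      }
    }
    ncyc[a] <- tot_cycles
    if (tot_cycles >= 2 && tot_span > 0) freq[a] <- tot_cycles / tot_span
    if (length(per_means) > 0) {
      curv[a] <- mean(per_means)
      curv_peak[a] <- mean(per_peaks)
    }
  }
  amp_px <- fr$amplitude_px
  amp_px[!fr$valid] <- NA
  amp_filled <- zoo::na.approx(amp_px, na.rm = FALSE, maxgap = max_gap)
  if (length(gamma_cycles) > 0) {
    peaks <- vapply(gamma_cycles, function(iv) {
      vals <- amp_filled[iv[1]:(iv[2] - 1L)]
      if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
    }, 0)
    amplitude_mean_px <- mean(peaks, na.rm = TRUE)
  } else {
    amplitude_mean_px <- mean(amp_px, na.rm = TRUE)
  }
  structure(list(freq_hz = freq,
                 half_cycle_curvature_deg = curv,
                 curvature_peak_deg = curv_peak,
                 amplitude_mean_px = amplitude_mean_px,
                 amplitude_mean_bl = amplitude_mean_px / trace$body_length_px,
                 n_cycles = ncyc,
                 invalid_fraction = mean(!fr$valid),
                 n_frames = nrow(fr)),
            class = "gait_summary")
}

#' @export
print.gait_summary <- function(x, ...) {
  cat("Gait summary\n")
  cat(sprintf("  frames: %d (%.1f%% invalid)\n",
              x$n_frames, 100 * x$invalid_fraction))
  for (a in c("alpha", "beta", "gamma")) {
    cat(sprintf("  %-5s freq %6.2f Hz  half-cycle curvature %6.2f deg  (%g cycles)\n",
                a, x$freq_hz[a], x$half_cycle_curvature_deg[a], x$n_cycles[a]))
  }
  cat(sprintf("  tail-beat amplitude: %.2f px = %.4f BL\n",
              x$amplitude_mean_px, x$amplitude_mean_bl))
  invisible(x)
}
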