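#' Per-frame validity check
#'
#' Implements the frame-level checks applied at the different stages of
#' the pipeline: a frame is invalid when no blob was selected
#' (`no_blob`), when more than one candidate passed the selection
#' criteria while a single blob is expected (`multiple_candidates`), or
#' when any skeleton pixel falls outside the selected blob
#' (`skeleton_outside_blob`). If every check passes the frame is valid.
#'
#' @param blob Selected `"fish_blob"` or `NULL`.
#' @param skeleton A `"skeleton_path"` or `NULL`.
#' @param policy A [validity_policy()].
#' @param n_candidates Number of blobs that passed the selection criteria.
#' @return List with elements `valid` (logical) and `reason` (empty
#'   string when valid).
#' @export
validate_frame <- function(blob, skeleton, policy, n_candidates = NULL) {
  if (is.null(blob)) return(list(valid = FALSE, reason = "no_blob"))
  if (is.null(n_candidates)) n_candidates <- attr(blob, "n_candidates") %||% 1L
  if (policy$expect_single_blob && n_candidates > 1L)
    return(list(valid = FALSE, reason = "multiple_candidates"))
  if (policy$require_skeleton_in_blob && !is.null(skeleton)) {
    keys <- paste(blob$pixels[, 1], blob$pixels[, 2])
    pk <- paste(round(skeleton$points[, 1]), round(skeleton$points[, 2]))
    if (!all(pk %in% keys))
      return(list(valid = FALSE, reason = "skeleton_outside_blob"))
  }
  list(valid = TRUE, reason = "")
}

#' Whole-video acceptance rule
#'
#' A video enters the evaluation only when strictly less than
#' `policy$max_invalid_fraction` of its frames are invalid (default 10%):
#' a video with exactly 10% invalid frames is rejected.
#'
#' @param reports Data frame of per-frame reports (needs a `valid` column).
#' @param policy A [validity_policy()].
#' @return List with `accepted` (logical) and `invalid_fraction`.
#' @export
accept_video <- function(reports, policy) {
  if (is.null(reports) || nrow(reports) == 0L)
    stop_gaitkin("empty report list", "gaitkin_bad_input")
  frac <- mean(!reports$valid)
  list(accepted = frac < policy$max_invalid_fraction, invalid_fraction = frac)
}

# shift blob coordinates from clip-local to absolute frame coordinates
offset_blob <- function(blob, dx, dy) {
  blob$pixels[, 1] <- blob$pixels[, 1] + dx
  blob$pixels[, 2] <- blob$pixels[, 2] + dy
  blob$bbox <- roi(blob$bbox$x0 + dx, blob$bbox$y0 + dy,
                   blob$bbox$width, blob$bbox$height)
  blob$centroid <- blob$centroid + c(dx, dy)
  blob
}

#' Analyze a fish-swimming video
#'
#' Runs the full kinematic pipeline on a video: per frame, preprocessing
#' (normalization, contrast stretch, Gaussian smoothing), motion-based
#' clipping of the region of interest, Otsu binarization, blob detection
#' and fish-blob selection, Zhang-Suen skeletonization, dorsal-path
#' extraction and orientation, placement of the four equidistant points
#' A--D, and computation of the inter-segment angles and tail-beat
#' amplitude. Per-frame validity checks are enforced throughout; the
#' video-level summary (tail-beat frequency, half-cycle curvature,
#' amplitude) is computed only when the video passes the invalid-frame
#' acceptance rule, although per-frame reports are always returned.
#'
#' @param source A video: path to an uncompressed AVI file or a directory
#'   of PNG frames, a list of frame matrices, a 3-D array
#'   (height x width x frames), or a `"synth_video"`.
#' @param config A [gait_config()].
#' @return An object of class `"gait_analysis"`: list with `trace`
#'   ([gait_trace()]), `summary` (a `"gait_summary"`, or `NULL` when the
#'   video is rejected), `reports` (per-frame validity data frame),
#'   `accepted`, `invalid_fraction`, `stage_log` (invalid-reason
#'   histogram) and `config`.
#' @export
analyze_video <- function(source, config = gait_config()) {
  frames <- as_frame_stack(source)
  n_all <- length(frames)
  if (n_all == 0L) stop_gaitkin("source has zero frames", "gaitkin_io_error")

  # optional analysis window (milliseconds), mirroring 1 s fragments
  first <- if (!is.null(config$start_ms))
    max(1L, 1L + round(config$start_ms / 1000 * config$fps)) else 1L
  last <- if (!is.null(config$duration_ms))
    min(n_all, first + round(config$duration_ms / 1000 * config$fps) - 1L) else n_all
  frames <- frames[first:last]
  n <- length(frames)

  analysis_roi <- config$roi %||% roi_of_frame(frames[[1]])
  check_roi_in_frame(analysis_roi, frames[[1]])
  ra <- roi_area(analysis_roi)

  pre <- lapply(frames, preprocess_frame, gaussian_sigma = config$gaussian_sigma,
                low_pct = config$low_pct, high_pct = config$high_pct)
  clips <- if (config$use_motion_clip && n >= 2L) {
    motion_clip(pre, analysis_roi, margin_px = config$margin_px,
                min_motion_frac = config$min_motion_frac,
                bg_frames = config$bg_frames,
                diff_threshold = config$diff_threshold)
  } else rep(list(analysis_roi), n)

  res <- vector("list", n)
  for (k in seq_len(n)) {
    res[[k]] <- analyze_one_frame(pre[[k]], clips[[k]], ra, config)
    res[[k]]$frame_index <- k - 1L
  }

  reports <- data.frame(
    frame_index = vapply(res, `[[`, 0L, "frame_index"),
    valid = vapply(res, `[[`, TRUE, "valid"),
    invalid_reason = vapply(res, `[[`, "", "reason"),
    stringsAsFactors = FALSE)

  arcs <- vapply(res, function(r) r$arc_length %||% NA_real_, 0)
  body_length <- config$body_length_px %||%
    stats::median(arcs[reports$valid], na.rm = TRUE)

  num <- function(field) vapply(res, function(r) r[[field]] %||% NA_real_, 0)
  fr <- data.frame(
    frame_index = reports$frame_index,
    time_ms = reports$frame_index / config$fps * 1000,
    valid = reports$valid,
    invalid_reason = reports$invalid_reason,
    Ax = num("Ax"), Ay = num("Ay"), Bx = num("Bx"), By = num("By"),
    Cx = num("Cx"), Cy = num("Cy"), Dx = num("Dx"), Dy = num("Dy"),
    alpha_deg = num("alpha"), beta_deg = num("beta"), gamma_deg = num("gamma"),
    amplitude_px = num("amplitude"),
    stringsAsFactors = FALSE)

  trace <- gait_trace(fr, config$fps, body_length)
  acc <- accept_video(reports, config$policy)
  summ <- if (acc$accepted && any(reports$valid))
    summarize_gait(trace, smooth_hz = config$smooth_hz,
                   max_gap = config$max_gap) else NULL
  stage_log <- table(factor(reports$invalid_reason[!reports$valid]))
  structure(list(trace = trace, summary = summ, reports = reports,
                 accepted = acc$accepted,
                 invalid_fraction = acc$invalid_fraction,
                 stage_log = stage_log, config = config),
            class = "gait_analysis")
}

# Segment + midline + kinematics for a single preprocessed frame.
analyze_one_frame <- function(frame, clip, roi_area_px, config) {
  out <- list(valid = FALSE, reason = "")
  region <- crop_frame(frame, clip)
  thr <- tryCatch(otsu_threshold(region), gaitkin_degenerate_histogram =
                    function(e) NULL)
  if (is.null(thr)) {
    out$reason <- "degenerate_histogram"
    return(out)
  }
  mask <- binarize(region, thr, config$polarity)
  blobs <- find_blobs(mask)
  blob <- select_fish_blob(blobs, config$criteria, roi_area_px)
  if (is.null(blob)) {
    out$reason <- if (length(blobs) == 0L) "no_blob" else {
      frac <- blobs[[1]]$area_px / roi_area_px
      if (frac < config$criteria$min_area_frac ||
          frac > config$criteria$max_area_frac) "blob_size" else "blob_shape"
    }
    return(out)
  }
  n_candidates <- attr(blob, "n_candidates")
  blob <- offset_blob(blob, clip$x0, clip$y0)
  if (config$policy$expect_single_blob && n_candidates > 1L) {
    out$reason <- "multiple_candidates"
    return(out)
  }

  bb <- blob$bbox
  bmask <- matrix(0L, bb$height, bb$width)
  bmask[cbind(blob$pixels[, 2] - bb$y0 + 1L,
              blob$pixels[, 1] - bb$x0 + 1L)] <- 1L
  skel <- skeletonize(bmask)
  path <- tryCatch(suppressWarnings(longest_path(skel)),
                   gaitkin_cyclic_skeleton = function(e) NULL)
  if (is.null(path) || path$arc_length_px <= 0) {
    out$reason <- "cyclic_skeleton"
    return(out)
  }
  path$points[, 1] <- path$points[, 1] + bb$x0
  path$points[, 2] <- path$points[, 2] + bb$y0
  path <- suppressWarnings(
    orient_path(path, blob, policy = config$orient_policy,
                head_x_sign = config$head_x_sign))
  if (config$extend_midline) path <- extend_path_ends(path, blob)

  chk <- validate_frame(blob, path, config$policy, n_candidates)
  if (!chk$valid) {
    out$reason <- chk$reason
    return(out)
  }

  pts <- equidistant_points(path, 4L)
  ang <- tryCatch(joint_angles(pts),
                  gaitkin_coincident_points = function(e) NULL)
  if (is.null(ang)) {
    out$reason <- "coincident_points"
    return(out)
  }
  list(valid = TRUE, reason = "",
       arc_length = path$arc_length_px,
       Ax = pts[1, 1], Ay = pts[1, 2], Bx = pts[2, 1], By = pts[2, 2],
       Cx = pts[3, 1], Cy = pts[3, 2], Dx = pts[4, 1], Dy = pts[4, 2],
       alpha = ang[["alpha_deg"]], beta = ang[["beta_deg"]],
       gamma = ang[["gamma_deg"]],
       amplitude = tail_amplitude(pts))
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf("<gait_analysis: %d frames at %g fps, %s (%.1f%% invalid)>\n",
              nrow(x$trace$frames), x$trace$fps,
              if (x$accepted) "ACCEPTED" else "REJECTED",
              100 * x$invalid_fraction))
  if (!is.null(x$summary)) print(x$summary)
  if (length(x$stage_log)) {
    cat("  invalid reasons:\n")
    for (r in names(x$stage_log))
      cat(sprintf("    %s: %d\n", r, x$stage_log[[r]]))
  }
  invisible(x)
}

#' @export
summary.gait_analysis <- function(object, ...) {
  if (is.null(object$summary))
    message("video rejected by the invalid-frame rule; summary undefined")
  object$summary
}

#' @export
as.data.frame.gait_analysis <- function(x, ...) x$trace$frames

#' @export
plot.gait_analysis <- function(x, ...) {
  fr <- x$trace$frames
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(fr$time_ms, fr[, c("alpha_deg", "beta_deg", "gamma_deg")],
                    type = "l", lty = 1, col = c("black", "red3", "blue3"),
                    xlab = "time (ms)", ylab = "angle (deg)",
                    main = "Inter-segment angles", ...)
  graphics::legend("topright", legend = c(expression(alpha), expression(beta),
                                          expression(gamma)),
                   col = c("black", "red3", "blue3"), lty = 1, bty = "n")
  graphics::plot(fr$time_ms, fr$amplitude_px, type = "l",
                 xlab = "time (ms)", ylab = "amplitude (px)",
                 main = "Tail-beat amplitude")
  invisible(x)
}

#' Write per-frame kinematics to CSV / summary to JSON
#'
#' The CSV has one row per frame: `frame_index`, `time_ms`, `valid`,
#' `invalid_reason`, the A--D coordinates, the three angles and the
#' amplitude in px and BL. The JSON mirrors the `"gait_summary"` fields
#' and echoes the configuration and package version.
#'
#' @param result A `"gait_analysis"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gait_csv <- function(result, path) {
  utils::write.csv(result$trace$frames, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gait_csv
#' @export
write_gait_json <- function(result, path) {
  s <- result$summary
  cfg <- result$config
  cfg$criteria <- unclass(cfg$criteria)
  cfg$policy$blob_criteria <- NULL
  cfg$policy <- unclass(cfg$policy)
  if (!is.null(cfg$roi)) cfg$roi <- unclass(cfg$roi)
  payload <- list(
    accepted = result$accepted,
    invalid_fraction = result$invalid_fraction,
    body_length_px = result$trace$body_length_px,
    summary = if (is.null(s)) NULL else unclass(s),
    config = unclass(cfg),
    software = paste0("gaitkin ", as.character(utils::packageVersion("gaitkin"))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' Rebuild a gait trace from a per-frame CSV
#'
#' Reads a CSV written by [write_gait_csv()] so a summary can be
#' recomputed without re-running segmentation.
#'
#' @param path CSV path.
#' @return A [gait_trace()].
#' @export
read_gait_csv <- function(path) {
  fr <- utils::read.csv(path, stringsAsFactors = FALSE)
  fr$invalid_reason[is.na(fr$invalid_reason)] <- ""
  dt <- diff(fr$time_ms)
  fps <- 1000 / stats::median(dt)
  bl <- stats::median(fr$amplitude_px / fr$amplitude_bl, na.rm = TRUE)
  fr$amplitude_bl <- NULL
  gait_trace(fr, fps, bl)
}
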