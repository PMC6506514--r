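#' Rectangular region of interest
#'
#' Defines the analysis region in a frame, following the on-disk config
#' convention: 0-based top-left origin and half-open extents, i.e. the
#' region covers columns `[x0, x0 + width)` and rows `[y0, y0 + height)`.
#'
#' @param x0,y0 Non-negative integer offsets of the top-left corner.
#' @param width,height Positive integer extents in pixels.
#' @return An object of class `"roi"`.
#' @export
roi <- function(x0, y0, width, height) {
  if (x0 < 0 || y0 < 0 || width <= 0 || height <= 0)
    stop_gaitkin("roi requires x0, y0 >= 0 and width, height > 0",
                 "gaitkin_bad_input")
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 width = as.integer(width), height = as.integer(height)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi [%d, %d) x [%d, %d)>\n",
              x$x0, x$x0 + x$width, x$y0, x$y0 + x$height))
  invisible(x)
}

roi_area <- function(r) as.numeric(r$width) * as.numeric(r$height)

roi_of_frame <- function(frame) roi(0, 0, ncol(frame), nrow(frame))

check_roi_in_frame <- function(r, frame) {
  if (r$x0 + r$width > ncol(frame) || r$y0 + r$height > nrow(frame))
    stop_gaitkin("roi extends outside the frame", "gaitkin_bad_input")
  invisible(r)
}

# matrix row/col index ranges covered by an roi
roi_rows <- function(r) (r$y0 + 1L):(r$y0 + r$height)
roi_cols <- function(r) (r$x0 + 1L):(r$x0 + r$width)

crop_frame <- function(frame, r) frame[roi_rows(r), roi_cols(r), drop = FALSE]

roi_intersect <- function(a, b) {
  x0 <- max(a$x0, b$x0); y0 <- max(a$y0, b$y0)
  x1 <- min(a$x0 + a$width, b$x0 + b$width)
  y1 <- min(a$y0 + a$height, b$y0 + b$height)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  roi(x0, y0, x1 - x0, y1 - y0)
}

#' Blob selection criteria
#'
#' Size and shape gates used to pick the fish among detected blobs. Areas
#' are expressed as fractions of the region-of-interest area so the same
#' criteria transfer across image resolutions; elongation is the
#' major/minor axis ratio from second central moments; solidity is blob
#' area over convex-hull area. Defaults describe an adult zebrafish
#' silhouette (elongated, slightly non-convex because of the fins). For
#' fin-less synthetic silhouettes a `max_solidity` of 1 is appropriate.
#'
#' @param min_area_frac,max_area_frac Admissible blob area as a fraction
#'   of ROI area, in (0, 1).
#' @param min_elongation Minimum major/minor axis ratio (>= 1).
#' @param min_solidity,max_solidity Admissible solidity range in (0, 1].
#' @return An object of class `"selection_criteria"`.
#' @export
selection_criteria <- function(min_area_frac = 0.002, max_area_frac = 0.25,
                               min_elongation = 2.5,
                               min_solidity = 0.3, max_solidity = 0.95) {
  if (min_area_frac >= max_area_frac)
    stop_gaitkin("min_area_frac must be < max_area_frac", "gaitkin_bad_input")
  if (min_solidity > max_solidity)
    stop_gaitkin("min_solidity must be <= max_solidity", "gaitkin_bad_input")
  structure(list(min_area_frac = min_area_frac, max_area_frac = max_area_frac,
                 min_elongation = min_elongation,
                 min_solidity = min_solidity, max_solidity = max_solidity),
            class = "selection_criteria")
}

#' Per-frame and per-video validity policy
#'
#' Encodes the validity checks applied to every frame (a single qualifying
#' blob, skeleton contained in that blob) and the whole-video acceptance
#' rule: a video is used only when strictly less than
#' `max_invalid_fraction` of its frames are invalid.
#'
#' @param expect_single_blob If `TRUE`, more than one blob passing the
#'   selection criteria invalidates the frame.
#' @param blob_criteria A [selection_criteria()] object.
#' @param require_skeleton_in_blob If `TRUE`, every skeleton pixel must lie
#'   inside the selected blob.
#' @param max_invalid_fraction Rejection threshold on the invalid-frame
#'   fraction, in (0, 1); the video is accepted iff
#'   `invalid_fraction < max_invalid_fraction` (strict).
#' @return An object of class `"validity_policy"`.
#' @export
validity_policy <- function(expect_single_blob = TRUE,
                            blob_criteria = selection_criteria(),
                            require_skeleton_in_blob = TRUE,
                            max_invalid_fraction = 0.10) {
  if (!(max_invalid_fraction > 0 && max_invalid_fraction < 1))
    stop_gaitkin("max_invalid_fraction must be in (0, 1)", "gaitkin_bad_input")
  structure(list(expect_single_blob = isTRUE(expect_single_blob),
                 blob_criteria = blob_criteria,
                 require_skeleton_in_blob = isTRUE(require_skeleton_in_blob),
                 max_invalid_fraction = max_invalid_fraction),
            class = "validity_policy")
}

#' Analysis configuration
#'
#' Bundles every tunable of the video-analysis pipeline with its default.
#' All values are exposed here and in the flat key-value config file read
#' by the command-line tool (see [read_config_file()]).
#'
#' @param roi Analysis region ([roi()]) or `NULL` for the full frame.
#' @param fps Acquisition rate in frames per second.
#' @param gaussian_sigma Gaussian smoothing sigma in pixels (0 disables).
#' @param low_pct,high_pct Percentiles mapped to 0 and 255 by the contrast
#'   stretch.
#' @param polarity `"dark_fish"` (silhouette imaging, default) or
#'   `"bright_fish"`.
#' @param criteria Blob [selection_criteria()].
#' @param policy [validity_policy()] for frame/video validity.
#' @param use_motion_clip Enable motion-based clipping of the ROI.
#' @param bg_frames Number of leading frames whose per-pixel median forms
#'   the motion background.
#' @param diff_threshold Intensity-difference threshold for "changed"
#'   pixels in motion detection.
#' @param margin_px Dilation margin around the motion bounding box.
#' @param min_motion_frac Below this changed-pixel fraction the full ROI is
#'   used (fallback).
#' @param orient_policy `"thickness"` (head is the thicker end) or
#'   `"fixed_direction"`.
#' @param head_x_sign `-1` if the head is the endpoint with smaller x
#'   (fish facing upstream on the left), `+1` otherwise; used by the
#'   fixed-direction policy and as tie-break fallback.
#' @param extend_midline Extend the thinned path along its end tangents to
#'   the blob boundary, compensating the end-shrink of thinning.
#' @param body_length_px Known body length in pixels (e.g. a measured
#'   standard length); `NULL` estimates it as the median midline arc
#'   length over valid frames.
#' @param smooth_hz Low-pass cutoff (Hz) used when locating half cycles.
#' @param max_gap Maximum invalid-frame gap (frames) bridged by linear
#'   interpolation; longer gaps split the trace.
#' @param start_ms,duration_ms Optional analysis window in milliseconds.
#' @return An object of class `"gait_config"`.
#' @export
gait_config <- function(roi = NULL, fps = 1000,
                        gaussian_sigma = 1.5, low_pct = 1, high_pct = 99,
                        polarity = c("dark_fish", "bright_fish"),
                        criteria = selection_criteria(),
                        policy = validity_policy(blob_criteria = criteria),
                        use_motion_clip = TRUE, bg_frames = 25,
                        diff_threshold = 10, margin_px = 10,
                        min_motion_frac = 1e-4,
                        orient_policy = c("thickness", "fixed_direction"),
                        head_x_sign = -1, extend_midline = TRUE,
                        body_length_px = NULL,
                        smooth_hz = 25, max_gap = 20,
                        start_ms = NULL, duration_ms = NULL) {
  polarity <- match.arg(polarity)
  orient_policy <- match.arg(orient_policy)
  if (fps <= 0) stop_gaitkin("fps must be positive", "gaitkin_bad_input")
  policy$blob_criteria <- criteria
  structure(list(roi = roi, fps = fps, gaussian_sigma = gaussian_sigma,
                 low_pct = low_pct, high_pct = high_pct, polarity = polarity,
                 criteria = criteria, policy = policy,
                 use_motion_clip = use_motion_clip, bg_frames = bg_frames,
                 diff_threshold = diff_threshold, margin_px = margin_px,
                 min_motion_frac = min_motion_frac,
                 orient_policy = orient_policy, head_x_sign = head_x_sign,
                 extend_midline = extend_midline,
                 body_length_px = body_length_px,
                 smooth_hz = smooth_hz, max_gap = max_gap,
                 start_ms = start_ms, duration_ms = duration_ms),
            class = "gait_config")
}

#' Read / write a flat key-value config file
#'
#' The on-disk format is one `key = value` pair per line; `#` starts a
#' comment; vector values are comma-separated (e.g. `roi = 0,0,512,160`).
#' Unknown keys are rejected. [read_config_file()] returns a
#' [gait_config()] with the file's values overriding the defaults.
#'
#' @param path File path.
#' @return For `read_config_file`, a `gait_config`; `write_config_file`
#'   returns `path` invisibly.
#' @export
read_config_file <- function(path) {
  kv <- parse_kv_file(path)
  cfg <- gait_config()
  crit <- cfg$criteria; pol <- cfg$policy
  for (key in names(kv)) {
    val <- kv[[key]]
    if (key == "roi") {
      if (length(val) != 4) stop_gaitkin("roi needs 4 values", "gaitkin_bad_input")
      cfg$roi <- roi(val[1], val[2], val[3], val[4])
    } else if (key %in% names(crit)) {
      crit[[key]] <- val
    } else if (key %in% c("expect_single_blob", "require_skeleton_in_blob",
                          "max_invalid_fraction")) {
      pol[[key]] <- val
    } else if (key %in% names(cfg)) {
      cfg[[key]] <- val
    } else {
      stop_gaitkin(sprintf("unknown config key '%s'", key), "gaitkin_bad_input")
    }
  }
  cfg$criteria <- crit
  pol$blob_criteria <- crit
  cfg$policy <- pol
  cfg
}

#' @rdname read_config_file
#' @param cfg A [gait_config()] object to serialize.
#' @export
write_config_file <- function(cfg, path) {
  fmt <- function(v) {
    if (is.logical(v)) return(ifelse(v, "true", "false"))
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = ",")
  }
  lines <- character(0)
  add <- function(k, v) {
    if (!is.null(v)) lines <<- c(lines, sprintf("%s = %s", k, fmt(v)))
  }
  if (!is.null(cfg$roi))
    add("roi", c(cfg$roi$x0, cfg$roi$y0, cfg$roi$width, cfg$roi$height))
  scalars <- c("fps", "gaussian_sigma", "low_pct", "high_pct", "polarity",
               "use_motion_clip", "bg_frames", "diff_threshold", "margin_px",
               "min_motion_frac", "orient_policy", "head_x_sign",
               "extend_midline", "body_length_px", "smooth_hz", "max_gap",
               "start_ms", "duration_ms")
  for (k in scalars) add(k, cfg[[k]])
  for (k in names(cfg$criteria)) add(k, cfg$criteria[[k]])
  add("expect_single_blob", cfg$policy$expect_single_blob)
  add("require_skeleton_in_blob", cfg$policy$require_skeleton_in_blob)
  add("max_invalid_fraction", cfg$policy$max_invalid_fraction)
  writeLines(lines, path)
  invisible(path)
}

# parse "key = value" lines into a named list of typed values
parse_kv_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3)
      stop_gaitkin(sprintf("cannot parse config line: '%s'", ln),
                   "gaitkin_bad_input")
    key <- m[2]
    raw <- trimws(strsplit(m[3], ",")[[1]])
    val <- suppressWarnings(as.numeric(raw))
    if (any(is.na(val))) {
      low <- tolower(raw)
      if (all(low %in% c("true", "false"))) val <- low == "true"
      else val <- gsub("^\"|\"$", "", raw)
    }
    out[[key]] <- val
  }
  out
}
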