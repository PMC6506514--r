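#' Normalize, contrast-stretch and smooth a frame
#'
#' Pre-processing applied before thresholding: intensities are linearly
#' re-scaled so the `low_pct` percentile maps to 0 and the `high_pct`
#' percentile to 255 (values outside are clipped). Saturating the extreme
#' percentiles suppresses faint structures such as fins before
#' binarization. A Gaussian blur with `gaussian_sigma` then reduces pixel
#' noise (`sigma = 0` disables it). A constant frame degenerates to an
#' all-zero output.
#'
#' @param frame Numeric frame matrix (intensities in \[0, 255\]).
#' @param gaussian_sigma Blur sigma in pixels (>= 0).
#' @param low_pct,high_pct Stretch percentiles, `0 <= low_pct < high_pct <= 100`.
#' @return A frame matrix of the same dimensions.
#' @export
preprocess_frame <- function(frame, gaussian_sigma = 1.5,
                             low_pct = 1, high_pct = 99) {
  assert_frame(frame)
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stop_gaitkin("need 0 <= low_pct < high_pct <= 100", "gaitkin_bad_input")
  if (gaussian_sigma < 0)
    stop_gaitkin("gaussian_sigma must be >= 0", "gaitkin_bad_input")
  qs <- stats::quantile(frame, c(low_pct, high_pct) / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    out <- matrix(0, nrow(frame), ncol(frame))
  } else {
    out <- clamp((frame - qs[1]) / (qs[2] - qs[1]) * 255, 0, 255)
  }
  if (gaussian_sigma > 0) {
    # gblur needs the kernel to fit the image; radius is 2*ceiling(3*sigma)+1
    out <- EBImage::gblur(out, sigma = gaussian_sigma, boundary = "replicate")
    out <- clamp(out, 0, 255)
  }
  out
}

#' Motion-based clipping of the region of interest
#'
#' Localizes the moving fish to shrink the region that later stages must
#' process. A per-pixel background is the median of the first `bg_frames`
#' frames; per frame, pixels whose absolute difference from the background
#' exceeds `diff_threshold` are "changed". The bounding box of changed
#' pixels, dilated by `margin_px` and intersected with `roi`, is returned.
#' If the changed fraction is below `min_motion_frac` (e.g. an empty,
#' static scene) the full `roi` is returned as a fallback.
#'
#' @param frames List of frame matrices (>= 2 for motion detection; a
#'   single frame returns the full ROI with a `"warning"` attribute).
#' @param roi Analysis [roi()].
#' @param margin_px Dilation margin in pixels.
#' @param min_motion_frac Fallback threshold on the changed-pixel fraction.
#' @param bg_frames Number of leading frames in the background median.
#' @param diff_threshold Intensity difference defining a changed pixel.
#' @return A list with one [roi()] per frame (each a subset of `roi`).
#' @export
motion_clip <- function(frames, roi, margin_px = 10, min_motion_frac = 1e-4,
                        bg_frames = 25, diff_threshold = 10) {
  if (length(frames) < 1L) stop_gaitkin("no frames", "gaitkin_bad_input")
  check_roi_in_frame(roi, frames[[1]])
  if (length(frames) < 2L) {
    out <- list(roi)
    attr(out, "warning") <- "single frame: motion detection skipped"
    return(out)
  }
  k <- min(bg_frames, length(frames))
  stack <- vapply(frames[seq_len(k)], function(f) crop_frame(f, roi),
                  matrix(0, roi$height, roi$width))
  bg <- apply(stack, c(1, 2), stats::median)
  lapply(frames, function(f) {
    d <- abs(crop_frame(f, roi) - bg) > diff_threshold
    if (mean(d) < min_motion_frac) return(roi)
    rows <- range(which(rowSums(d) > 0))
    cols <- range(which(colSums(d) > 0))
    box <- roi(max(0, roi$x0 + cols[1] - 1 - margin_px),
               max(0, roi$y0 + rows[1] - 1 - margin_px),
               cols[2] - cols[1] + 1 + 2 * margin_px,
               rows[2] - rows[1] + 1 + 2 * margin_px)
    roi_intersect(box, roi)
  })
}

#' Otsu's optimal threshold
#'
#' Computes the threshold `t` in \[0, 255\] maximizing the between-class
#' variance of the 256-bin intensity histogram, i.e. the optimal cut
#' separating object from background. Ties are broken toward the smallest
#' maximizing `t`. A region whose histogram occupies a single bin carries
#' no separating information and raises a degenerate-histogram error
#' (callers mark the frame invalid).
#'
#' @param region Numeric frame matrix (or vector) of intensities in
#'   \[0, 255\]; non-integer values are binned by `floor`.
#' @return Integer threshold in \[0, 255\].
#' @export
otsu_threshold <- function(region) {
  v <- clamp(floor(as.numeric(region)), 0, 255)
  if (length(v) == 0L) stop_gaitkin("empty region", "gaitkin_bad_input")
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L)
    stop_gaitkin("constant region: histogram is degenerate",
                 "gaitkin_degenerate_histogram")
  p <- h / sum(h)
  lev <- 0:255
  w0 <- cumsum(p)                 # P(I <= t)
  mu <- cumsum(p * lev)           # partial mean
  mu_t <- mu[256]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf   # w0 = 0 or 1: no split
  as.integer(which.max(sigma_b) - 1L)    # which.max -> smallest maximizer
}

#' Binarize a region at a threshold
#'
#' @param region Numeric frame matrix.
#' @param threshold Integer threshold in \[0, 255\].
#' @param polarity `"dark_fish"`: foreground where intensity `<= threshold`
#'   (silhouette imaging, the default convention package-wide);
#'   `"bright_fish"`: foreground where intensity `> threshold`.
#' @return An integer 0/1 matrix of the same dimensions (1 = foreground).
#' @export
binarize <- function(region, threshold, polarity = c("dark_fish", "bright_fish")) {
  polarity <- match.arg(polarity)
  if (threshold < 0 || threshold > 255)
    stop_gaitkin("threshold must be in [0, 255]", "gaitkin_bad_input")
  m <- if (polarity == "dark_fish") region <= threshold else region > threshold
  mask <- matrix(as.integer(m), nrow(region), ncol(region))
  mask
}

# 8-connected labeling of a 0/1 mask -> integer label matrix (0 = bg).
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  fg <- which(mask != 0)
  if (length(fg) == 0L) return(lab)
  nr <- nrow(mask)
  pos <- seq_along(fg)
  idx <- fg
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  lookup <- integer(length(mask)); lookup[idx] <- pos
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 <= ncol(mask) & c2 >= 1L
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lookup[nb] > 0L
    if (any(hit))
      edges <- c(edges, rbind(pos[ok][hit], lookup[nb][hit]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

#' Detect blobs (8-connected components) in a binary mask
#'
#' Each foreground component is summarized by its pixel set, area,
#' bounding box, centroid, elongation (major/minor axis ratio from second
#' central moments, with the 1/12 per-pixel variance term so a single
#' pixel has elongation 1) and solidity (area over the convex-hull area of
#' the pixel squares).
#'
#' @param mask 0/1 matrix (1 = foreground).
#' @return A list of `"fish_blob"` objects sorted by decreasing area;
#'   empty list for an empty mask.
#' @export
find_blobs <- function(mask) {
  lab <- label_components8(mask)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  nr <- nrow(mask)
  idx <- which(lab > 0L)
  memb <- lab[idx]
  xs <- ((idx - 1L) %/% nr)       # 0-based
  ys <- ((idx - 1L) %% nr)
  blobs <- lapply(seq_len(nlab), function(i) {
    sel <- memb == i
    make_blob(xs[sel], ys[sel])
  })
  blobs[order(-vapply(blobs, function(b) b$area_px, 0))]
}

make_blob <- function(xs, ys) {
  n <- length(xs)
  cx <- mean(xs); cy <- mean(ys)
  # second central moments incl. the unit-square pixel term
  mxx <- mean((xs - cx)^2) + 1 / 12
  myy <- mean((ys - cy)^2) + 1 / 12
  mxy <- mean((xs - cx) * (ys - cy))
  tr <- mxx + myy
  det_ <- mxx * myy - mxy^2
  disc <- sqrt(max(0, tr^2 / 4 - det_))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
  elong <- sqrt(l1 / l2)
  # convex hull of the pixel squares' corners
  corn_x <- c(xs - 0.5, xs + 0.5, xs - 0.5, xs + 0.5)
  corn_y <- c(ys - 0.5, ys - 0.5, ys + 0.5, ys + 0.5)
  hull <- grDevices::chull(corn_x, corn_y)
  hx <- corn_x[hull]; hy <- corn_y[hull]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  structure(list(pixels = cbind(x = xs, y = ys),
                 area_px = n,
                 bbox = roi(min(xs), min(ys),
                            max(xs) - min(xs) + 1L, max(ys) - min(ys) + 1L),
                 centroid = c(x = cx, y = cy),
                 elongation = elong,
                 solidity = min(1, n / max(hull_area, 1e-12))),
            class = "fish_blob")
}

#' @export
print.fish_blob <- function(x, ...) {
  cat(sprintf("<blob: %d px, centroid (%.1f, %.1f), elongation %.2f, solidity %.2f>\n",
              x$area_px, x$centroid[1], x$centroid[2], x$elongation, x$solidity))
  invisible(x)
}

blob_qualifies <- function(blob, criteria, roi_area) {
  frac <- blob$area_px / roi_area
  frac >= criteria$min_area_frac && frac <= criteria$max_area_frac &&
    blob$elongation >= criteria$min_elongation &&
    blob$solidity >= criteria$min_solidity &&
    blob$solidity <= criteria$max_solidity
}

#' Select the blob assumed to be the fish
#'
#' Among the blobs whose area fraction of the ROI, elongation and solidity
#' fall inside `criteria`, returns the largest (ties: greater elongation,
#' then smaller bounding-box x0 — a total order). Returns `NULL` when no
#' blob qualifies; the number of qualifying candidates is attached as
#' attribute `"n_candidates"` (used by the single-blob validity check).
#'
#' @param blobs List of blobs from [find_blobs()].
#' @param criteria A [selection_criteria()].
#' @param roi_area Area of the analysis ROI in pixels.
#' @return A `"fish_blob"` or `NULL`.
#' @export
select_fish_blob <- function(blobs, criteria, roi_area) {
  if (roi_area <= 0) stop_gaitkin("roi_area must be > 0", "gaitkin_bad_input")
  ok <- Filter(function(b) blob_qualifies(b, criteria, roi_area), blobs)
  if (length(ok) == 0L) return(NULL)
  o <- order(-vapply(ok, function(b) as.numeric(b$area_px), 0),
             -vapply(ok, function(b) b$elongation, 0),
             vapply(ok, function(b) b$bbox$x0, 0L))
  out <- ok[[o[1]]]
  attr(out, "n_candidates") <- length(ok)
  out
}
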