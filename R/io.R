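# Frame ingestion and export: PNG frame directories, uncompressed AVI,
# ground-truth CSV, luminance conversion.

#' Coerce a video source to a list of frame matrices
#'
#' Accepts a list of matrices, a 3-D array (height x width x frames), a
#' `"synth_video"`, a directory of PNG frames (sorted by file name) or an
#' uncompressed AVI file. Color frames are converted to luminance with
#' ITU-R BT.601 weights (0.299 R + 0.587 G + 0.114 B).
#'
#' @param source See above.
#' @return List of numeric frame matrices with intensities in \[0, 255\].
#' @export
as_frame_stack <- function(source) {
  if (inherits(source, "synth_video")) return(source$frames)
  if (is.list(source)) {
    lapply(source, assert_frame)
    return(source)
  }
  if (is.array(source) && length(dim(source)) == 3L)
    return(lapply(seq_len(dim(source)[3]), function(k) source[, , k]))
  if (is.matrix(source)) return(list(source))
  if (is.character(source) && length(source) == 1L) {
    if (dir.exists(source)) return(read_png_dir(source))
    if (file.exists(source)) {
      if (grepl("\\.avi$", source, ignore.case = TRUE))
        return(read_avi(source))
      stop_gaitkin("unsupported video file (use uncompressed AVI or a PNG directory)",
                   "gaitkin_io_error")
    }
    stop_gaitkin(sprintf("source '%s' not found", source), "gaitkin_io_error")
  }
  stop_gaitkin("unsupported source type", "gaitkin_io_error")
}

luminance601 <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

read_png_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L)
    stop_gaitkin(sprintf("no PNG frames in '%s'", dir), "gaitkin_io_error")
  lapply(files, function(f) luminance601(png::readPNG(f)) * 255)
}

#' Write frames as a PNG directory
#'
#' @param frames List of frame matrices (or `"synth_video"`).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames_png <- function(frames, dir) {
  frames <- as_frame_stack(frames)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(frames)) {
    png::writePNG(clamp(frames[[k]], 0, 255) / 255,
                  file.path(dir, sprintf("frame_%06d.png", k - 1L)))
  }
  invisible(dir)
}

# ---- uncompressed AVI (RIFF, 8-bit palettized DIB frames) ----------------

w_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")
w_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
w_4cc <- function(con, s) writeBin(charToRaw(s), con)

#' Write frames as an uncompressed AVI file
#'
#' Produces a classic RIFF AVI with a single `vids` stream of 8-bit
#' palettized, uncompressed (BI_RGB) DIB frames with a grayscale palette
#' — the layout a high-speed camera writes when saving without
#' compression. Intensities are rounded to integers in \[0, 255\].
#'
#' @param frames List of frame matrices (or `"synth_video"`); all frames
#'   must share dimensions.
#' @param path Output file path.
#' @param fps Frame rate stored in the stream header.
#' @return `path`, invisibly.
#' @export
write_avi <- function(frames, path, fps = 1000) {
  frames <- as_frame_stack(frames)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  stride <- 4L * ((w + 3L) %/% 4L)
  fsize <- stride * h
  n <- length(frames)

  con <- file(path, "wb")
  on.exit(close(con))

  hdrl_size <- 4L + (8L + 56L) + (8L + 4L + (8L + 56L) + (8L + 40L + 1024L))
  movi_size <- 4L + n * (8L + fsize)
  idx_size <- n * 16L
  riff_size <- 4L + (8L + hdrl_size) + (8L + movi_size) + (8L + idx_size)

  w_4cc(con, "RIFF"); w_u32(con, riff_size); w_4cc(con, "AVI ")
  w_4cc(con, "LIST"); w_u32(con, hdrl_size); w_4cc(con, "hdrl")
  w_4cc(con, "avih"); w_u32(con, 56)
  w_u32(con, round(1e6 / fps)); w_u32(con, fsize * fps); w_u32(con, 0)
  w_u32(con, 0x10)  # AVIF_HASINDEX
  w_u32(con, n); w_u32(con, 0); w_u32(con, 1); w_u32(con, fsize)
  w_u32(con, w); w_u32(con, h); w_u32(con, rep(0, 4))
  w_4cc(con, "LIST"); w_u32(con, 4L + (8L + 56L) + (8L + 40L + 1024L))
  w_4cc(con, "strl")
  w_4cc(con, "strh"); w_u32(con, 56)
  w_4cc(con, "vids"); w_4cc(con, "DIB ")
  w_u32(con, 0); w_u16(con, c(0, 0)); w_u32(con, 0)
  w_u32(con, 1); w_u32(con, fps)        # scale, rate -> fps
  w_u32(con, 0); w_u32(con, n); w_u32(con, fsize); w_u32(con, 0); w_u32(con, 0)
  w_u16(con, c(0, 0, w, h))             # rcFrame
  w_4cc(con, "strf"); w_u32(con, 40L + 1024L)
  w_u32(con, 40); w_u32(con, w); w_u32(con, h); w_u16(con, 1); w_u16(con, 8)
  w_u32(con, 0)                         # BI_RGB
  w_u32(con, fsize); w_u32(con, 0); w_u32(con, 0); w_u32(con, 256); w_u32(con, 0)
  pal <- as.raw(t(cbind(0:255, 0:255, 0:255, 0)))   # B G R 0 per entry
  writeBin(pal, con)

  w_4cc(con, "LIST"); w_u32(con, movi_size); w_4cc(con, "movi")
  pad_cols <- stride - w
  for (f in frames) {
    w_4cc(con, "00db"); w_u32(con, fsize)
    m <- pmin(pmax(round(f), 0), 255)
    rows <- m[h:1, , drop = FALSE]                  # bottom-up
    if (pad_cols > 0) rows <- cbind(rows, matrix(0L, h, pad_cols))
    writeBin(as.raw(as.integer(t(rows))), con)
  }

  w_4cc(con, "idx1"); w_u32(con, idx_size)
  off <- 4L
  for (k in seq_len(n)) {
    w_4cc(con, "00db"); w_u32(con, 0x10); w_u32(con, off); w_u32(con, fsize)
    off <- off + 8L + fsize
  }
  invisible(path)
}

r_u32 <- function(raw, pos) {
  sum(as.integer(raw[pos:(pos + 3L)]) * c(1, 256, 65536, 16777216))
}

#' Read an uncompressed AVI file
#'
#' Supports single-stream AVI files with uncompressed (BI_RGB) 8-bit
#' palettized or 24-bit DIB frames, as written by [write_avi()] or a
#' camera saving without compression. 24-bit frames are converted to
#' luminance (ITU-R BT.601).
#'
#' @param path AVI file path.
#' @return List of numeric frame matrices (intensities 0--255). The frame
#'   rate from the stream header is attached as attribute `"fps"`.
#' @export
read_avi <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:4]) != "RIFF" || rawToChar(raw[9:12]) != "AVI ")
    stop_gaitkin("not an AVI file", "gaitkin_io_error")
  w <- h <- bits <- NULL; fps <- NA_real_
  pal_gray <- NULL
  frames <- list()
  pos <- 13L
  n_total <- length(raw)
  scan_chunks <- function(pos, end) {
    while (pos + 8L <= end) {
      cc <- rawToChar(raw[pos:(pos + 3L)])
      sz <- r_u32(raw, pos + 4L)
      body <- pos + 8L
      if (cc == "LIST") {
        scan_chunks(body + 4L, body + sz)
      } else if (cc == "strh") {
        scale <- r_u32(raw, body + 20L); rate <- r_u32(raw, body + 24L)
        if (scale > 0) fps <<- rate / scale
      } else if (cc == "strf") {
        w <<- r_u32(raw, body + 4L); h <<- r_u32(raw, body + 8L)
        bits <<- as.integer(raw[body + 14L]) + 256L * as.integer(raw[body + 15L])
        if (r_u32(raw, body + 16L) != 0)
          stop_gaitkin("compressed AVI streams are not supported",
                       "gaitkin_io_error")
        if (bits == 8L && sz >= 40L + 1024L) {
          pal <- raw[(body + 40L):(body + 40L + 1023L)]
          pal_gray <<- as.integer(pal[seq(3L, 1024L, by = 4L)])  # R channel
        }
      } else if (cc %in% c("00db", "00dc") && sz > 0) {
        frames[[length(frames) + 1L]] <<- raw[body:(body + sz - 1L)]
      }
      pos <- body + sz + (sz %% 2L)   # chunks are word-aligned
    }
  }
  scan_chunks(pos, n_total)
  if (is.null(w) || length(frames) == 0L)
    stop_gaitkin("no video frames found in AVI", "gaitkin_io_error")
  bpp <- bits %/% 8L
  stride <- 4L * ((w * bpp + 3L) %/% 4L)
  out <- lapply(frames, function(fr) {
    m <- matrix(as.integer(fr[seq_len(stride * h)]), nrow = stride, ncol = h)
    if (bpp == 1L) {
      px <- m[seq_len(w), h:1, drop = FALSE]         # undo bottom-up
      g <- if (!is.null(pal_gray)) matrix(pal_gray[px + 1L], w, h) else px
      t(g)
    } else {
      b <- m[seq(1L, by = 3L, length.out = w), h:1, drop = FALSE]
      g <- m[seq(2L, by = 3L, length.out = w), h:1, drop = FALSE]
      r <- m[seq(3L, by = 3L, length.out = w), h:1, drop = FALSE]
      t(0.299 * r + 0.587 * g + 0.114 * b)
    }
  })
  attr(out, "fps") <- fps
  out
}

#' Write synthetic ground truth as CSV
#'
#' @param video A `"synth_video"` from [generate_video()] (or its
#'   `ground_truth` data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(video, path) {
  gt <- if (inherits(video, "synth_video")) video$ground_truth else video
  utils::write.csv(gt, path, row.names = FALSE)
  invisible(path)
}

#' Write a debug overlay PNG for one frame
#'
#' Draws the selected blob outline, the extracted midline and the A--D
#' points over the frame; useful for visually auditing segmentation.
#'
#' @param frame Frame matrix.
#' @param path Output PNG path.
#' @param blob Optional `"fish_blob"`.
#' @param path_points Optional midline point matrix.
#' @param abcd Optional `4 x 2` matrix of the A--D points.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(frame, path, blob = NULL, path_points = NULL,
                              abcd = NULL) {
  img <- clamp(frame, 0, 255) / 255
  rgb <- array(rep(img, 3), dim = c(nrow(img), ncol(img), 3))
  put <- function(x, y, col) {
    r <- round(y) + 1L; c <- round(x) + 1L
    ok <- r >= 1 & r <= nrow(img) & c >= 1 & c <= ncol(img)
    for (ch in 1:3) rgb[cbind(r[ok], c[ok], ch)] <<- col[ch]
  }
  if (!is.null(blob)) {
    edge <- blob$pixels[border_pixels(blob), , drop = FALSE]
    put(edge[, 1], edge[, 2], c(0, 0.8, 0))
  }
  if (!is.null(path_points)) {
    pp <- if (inherits(path_points, "skeleton_path")) path_points$points else path_points
    put(pp[, 1], pp[, 2], c(1, 0, 0))
  }
  if (!is.null(abcd)) put(abcd[, 1], abcd[, 2], c(0, 0.4, 1))
  png::writePNG(rgb, path)
  invisible(path)
}

# logical index of blob pixels having a non-blob 4-neighbor
border_pixels <- function(blob) {
  keys <- paste(blob$pixels[, 1], blob$pixels[, 2])
  has_all <- rep(TRUE, nrow(blob$pixels))
  for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- paste(blob$pixels[, 1] + off[1], blob$pixels[, 2] + off[2])
    has_all <- has_all & nb %in% keys
  }
  !has_all
}
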