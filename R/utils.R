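# Internal helpers shared across modules.
#
# Conventions used package-wide:
#  * A frame is a numeric matrix [height x width] with intensities in
#    [0, 255]; row index = y + 1, column index = x + 1.
#  * Continuous point coordinates are 0-based pixel centers: the pixel at
#    matrix position [r, c] has center (x, y) = (c - 1, r - 1).
#  * Regions of interest are 0-based, half-open: [x0, x0 + w) x [y0, y0 + h).

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_gaitkin <- function(msg, class, call. = sys.call(-1)) {
  cond <- structure(
    class = c(class, "gaitkin_error", "error", "condition"),
    list(message = msg, call = call.)
  )
  stop(cond)
}

assert_frame <- function(frame, what = "frame") {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0L)
    stop_gaitkin(sprintf("%s must be a nonempty numeric matrix", what),
                 "gaitkin_bad_input")
  invisible(frame)
}

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards (keeps frame rendering a pure function
# of (cfg, frame_index) without perturbing user code).
with_private_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  code
}

# Cumulative arc length of an n x 2 polyline (Euclidean step lengths).
polyline_cumlen <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  d <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  c(0, cumsum(d))
}
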