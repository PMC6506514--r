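# Independent reference implementations used as test oracles. These are
# deliberately written in a different (naive, loop-based) style than the
# package code so the two cannot share a bug.

# Exhaustive Otsu: for every threshold t compute the two class weights and
# means from scratch and score the between-class variance; return the
# smallest maximizing t.
ref_otsu <- function(v) {
  v <- pmin(pmax(floor(as.numeric(v)), 0), 255)
  best_t <- NA_integer_
  best_score <- -Inf
  for (t in 0:255) {
    c0 <- v[v <= t]
    c1 <- v[v > t]
    if (length(c0) == 0 || length(c1) == 0) next
    w0 <- length(c0) / length(v)
    w1 <- 1 - w0
    score <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (score > best_score + 1e-12) {
      best_score <- score
      best_t <- t
    }
  }
  best_t
}

# Reference Zhang-Suen thinning, pixel-by-pixel loops. Neighborhood
# convention: P2 = (r-1, c), then clockwise P3 = (r-1, c+1), ... matching
# the published two-subiteration scheme.
ref_zhang_suen <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  pad <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  nbrs <- function(p, r, c) {
    c(p[r - 1, c], p[r - 1, c + 1], p[r, c + 1], p[r + 1, c + 1],
      p[r + 1, c], p[r + 1, c - 1], p[r, c - 1], p[r - 1, c - 1])
  }
  repeat {
    any_change <- FALSE
    for (phase in 1:2) {
      to_del <- NULL
      for (r in 2:(nrow(pad) - 1)) for (c in 2:(ncol(pad) - 1)) {
        if (pad[r, c] == 0L) next
        nb <- nbrs(pad, r, c)
        b <- sum(nb)
        if (b < 2 || b > 6) next
        seq9 <- c(nb, nb[1])
        a <- 0
        for (i in 1:8) if (seq9[i] == 0 && seq9[i + 1] == 1) a <- a + 1
        if (a != 1) next
        if (phase == 1) {
          if (nb[1] * nb[3] * nb[5] != 0) next
          if (nb[3] * nb[5] * nb[7] != 0) next
        } else {
          if (nb[1] * nb[3] * nb[7] != 0) next
          if (nb[1] * nb[5] * nb[7] != 0) next
        }
        to_del <- rbind(to_del, c(r, c))
      }
      if (!is.null(to_del)) {
        pad[to_del] <- 0L
        any_change <- TRUE
      }
    }
    if (!any_change) break
  }
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)]
}

# Weighted skeleton diameter by brute force: all-pairs shortest path
# lengths (Floyd-Warshall over the 8-adjacency pixel graph), maximized
# over pairs of degree-1 endpoint pixels. This is the dorsal path the
# extractor must find: side spurs shorter than the main axis are pruned.
ref_longest_path_length <- function(skel) {
  idx <- which(skel != 0, arr.ind = TRUE)
  n <- nrow(idx)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  deg <- rep(0, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    dr <- abs(idx[i, 1] - idx[j, 1]); dc <- abs(idx[i, 2] - idx[j, 2])
    if (dr <= 1 && dc <= 1) {
      d[i, j] <- if (dr + dc == 2) sqrt(2) else 1
      deg[i] <- deg[i] + 1
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  ends <- which(deg == 1)
  max(d[ends, ends][is.finite(d[ends, ends])])
}

# Dominant frequency from the discrete Fourier spectrum (excluding DC).
ref_fourier_peak_hz <- function(x, fps) {
  x <- x - mean(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(length(x) / 2))]
  freqs <- (seq_along(sp) - 1) * fps / length(x)
  freqs[which.max(sp)]
}

# Directed Hausdorff distance from point set a to point set b (n x 2).
directed_hausdorff <- function(a, b) {
  max(apply(a, 1, function(p) sqrt(min((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2))))
}

rigid_transform <- function(pts, theta, dx, dy) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(pts %*% t(R), 2, c(-dx, -dy))
}
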