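#' Zhang-Suen thinning
#'
#' Reduces a binary silhouette to a one-pixel-wide, 8-connected skeleton
#' with the classic two-subiteration parallel thinning algorithm. In each
#' subiteration a foreground pixel P1 with circular neighborhood
#' P2..P9 (P2 = north, P4 = east, P6 = south, P8 = west) is deleted when
#' 2 <= B(P1) <= 6, A(P1) = 1 (number of 0->1 transitions in
#' P2,P3,...,P9,P2) and the subiteration's two corner products are zero
#' (P2*P4*P6 = 0 and P4*P6*P8 = 0, then P2*P4*P8 = 0 and P2*P6*P8 = 0).
#' Both subiterations delete in parallel; iteration stops at a fixed
#' point. The output is a subset of the input foreground.
#'
#' @param mask 0/1 matrix with at least one foreground pixel.
#' @return A 0/1 matrix of the same dimensions containing the skeleton.
#' @export
skeletonize <- function(mask) {
  if (sum(mask) == 0) stop_gaitkin("empty mask", "gaitkin_bad_input")
  nr <- nrow(mask); nc <- ncol(mask)
  # zero padding so every foreground pixel has a full 3x3 neighborhood
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask != 0)
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbors in matrix terms: north = row - 1 (y up the screen is
      # row-down agnostic; only the circular order matters)
      P2 <- p[ri - 1L, ci];      P3 <- p[ri - 1L, ci + 1L]
      P4 <- p[ri, ci + 1L];      P5 <- p[ri + 1L, ci + 1L]
      P6 <- p[ri + 1L, ci];      P7 <- p[ri + 1L, ci - 1L]
      P8 <- p[ri, ci - 1L];      P9 <- p[ri - 1L, ci - 1L]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
           (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
           (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
           (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      if (sub == 1L) {
        corner <- (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        corner <- (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      del <- p[ri, ci] == 1L & B >= 2L & B <= 6L & A == 1L & corner
      if (any(del)) {
        q <- p[ri, ci]; q[del] <- 0L; p[ri, ci] <- q
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- p[ri, ci]
  dimnames(out) <- NULL
  out
}

# 8-adjacency graph of skeleton pixels; vertices in foreground order.
skeleton_graph <- function(skel) {
  idx <- which(skel != 0)
  nr <- nrow(skel)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  lookup <- integer(length(skel)); lookup[idx] <- seq_along(idx)
  edges <- integer(0); wts <- numeric(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(skel)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lookup[nb] > 0L
    if (any(hit)) {
      edges <- c(edges, rbind(which(ok)[hit], lookup[nb][hit]))
      wts <- c(wts, rep(if (all(off != 0L)) sqrt(2) else 1, sum(hit)))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  igraph::E(g)$weight <- wts
  list(g = g, x = cc - 1L, y = r - 1L)
}

#' Longest endpoint-to-endpoint path through a skeleton
#'
#' Builds the 8-adjacency graph of skeleton pixels (steps weighted 1
#' axially, sqrt(2) diagonally) and returns the maximum-arc-length simple
#' path between two endpoints (degree-1 pixels). This prunes spurious
#' side branches left by thinning, retaining the dorsal head-to-tail
#' curve. A skeleton without endpoints (a cycle) is an error and the
#' frame is marked invalid downstream; a disconnected skeleton is reduced
#' to its largest component with a warning.
#'
#' @param skel 0/1 skeleton matrix from [skeletonize()].
#' @return An object of class `"skeleton_path"`: list with `points`
#'   (ordered `n x 2` matrix of 0-based (x, y) pixel coordinates) and
#'   `arc_length_px`.
#' @export
longest_path <- function(skel) {
  if (sum(skel) == 0) stop_gaitkin("empty skeleton", "gaitkin_bad_input")
  sg <- skeleton_graph(skel)
  comp <- igraph::components(sg$g)
  if (comp$no > 1L) {
    warning("disconnected skeleton: using the largest component")
    keep <- which(comp$membership == which.max(comp$csize))
  } else keep <- seq_along(sg$x)
  g <- igraph::induced_subgraph(sg$g, keep)
  xs <- sg$x[keep]; ys <- sg$y[keep]
  if (igraph::vcount(g) == 1L) {
    return(structure(list(points = cbind(x = xs, y = ys), arc_length_px = 0),
                     class = "skeleton_path"))
  }
  ends <- which(igraph::degree(g) == 1L)
  if (length(ends) == 0L)
    stop_gaitkin("cyclic skeleton has no endpoints", "gaitkin_cyclic_skeleton")
  d <- igraph::distances(g, v = ends, to = ends)
  best <- which(d == max(d), arr.ind = TRUE)[1, ]
  vpath <- igraph::shortest_paths(g, from = ends[best[1]], to = ends[best[2]],
                                  output = "vpath")$vpath[[1]]
  v <- as.integer(vpath)
  pts <- cbind(x = xs[v], y = ys[v])
  structure(list(points = pts,
                 arc_length_px = sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))),
            class = "skeleton_path")
}

#' @export
print.skeleton_path <- function(x, ...) {
  cat(sprintf("<skeleton_path: %d points, arc length %.1f px>\n",
              nrow(x$points), x$arc_length_px))
  invisible(x)
}

#' Orient a skeleton path head-first
#'
#' Decides which end of the dorsal path is the head. The `"thickness"`
#' policy uses the blob's Euclidean distance transform: the endpoint whose
#' mean distance-to-boundary over its first 10% of arc length is larger is
#' the head (fish heads are thicker than caudal peduncles). An exact tie
#' falls back to `"fixed_direction"` with a warning: the head is the
#' endpoint with smaller x when `head_x_sign = -1` (fish face upstream),
#' larger x when `+1`. The same path is returned, possibly reversed, so
#' orientation is idempotent and independent of the input direction.
#'
#' @param path A `"skeleton_path"`.
#' @param blob The `"fish_blob"` the skeleton came from.
#' @param policy `"thickness"` or `"fixed_direction"`.
#' @param head_x_sign -1 or +1, see above.
#' @return The oriented `"skeleton_path"`, head first.
#' @export
orient_path <- function(path, blob, policy = c("thickness", "fixed_direction"),
                        head_x_sign = -1) {
  policy <- match.arg(policy)
  pts <- path$points
  n <- nrow(pts)
  if (n < 2L) return(path)
  flip <- FALSE
  if (policy == "thickness") {
    dt <- blob_distance_transform(blob)
    vals <- dt[cbind(pts[, 2] - blob$bbox$y0 + 1L,
                     pts[, 1] - blob$bbox$x0 + 1L)]
    cl <- polyline_cumlen(pts)
    tot <- cl[n]
    head_zone <- cl <= 0.1 * tot
    tail_zone <- cl >= 0.9 * tot
    m_start <- mean(vals[head_zone])
    m_end <- mean(vals[tail_zone])
    if (isTRUE(all.equal(m_start, m_end, tolerance = 1e-9))) {
      warning("thickness tie: falling back to fixed_direction")
      policy <- "fixed_direction"
    } else {
      flip <- m_end > m_start
    }
  }
  if (policy == "fixed_direction") {
    xa <- pts[1, 1]; xb <- pts[n, 1]
    flip <- if (head_x_sign < 0) xb < xa else xb > xa
  }
  if (flip) path$points <- pts[n:1, , drop = FALSE]
  path
}

# Euclidean distance transform of the blob over its bounding box
blob_distance_transform <- function(blob) {
  bb <- blob$bbox
  m <- matrix(0L, bb$height, bb$width)
  m[cbind(blob$pixels[, 2] - bb$y0 + 1L, blob$pixels[, 1] - bb$x0 + 1L)] <- 1L
  # pad so blob pixels touching the bbox edge still see background
  pm <- matrix(0L, bb$height + 2L, bb$width + 2L)
  pm[2:(bb$height + 1L), 2:(bb$width + 1L)] <- m
  d <- EBImage::distmap(pm, metric = "euclidean")
  d[2:(bb$height + 1L), 2:(bb$width + 1L), drop = FALSE]
}

# Extend both ends of an oriented path along the local tangent until the
# blob boundary, compensating the end-shrink of thinning (the skeleton of
# a rounded cap stops near the cap center, about one half-width short).
extend_path_ends <- function(path, blob) {
  bb <- blob$bbox
  inside <- matrix(FALSE, bb$height, bb$width)
  inside[cbind(blob$pixels[, 2] - bb$y0 + 1L,
               blob$pixels[, 1] - bb$x0 + 1L)] <- TRUE
  in_blob <- function(x, y) {
    r <- round(y) - bb$y0 + 1L; c <- round(x) - bb$x0 + 1L
    r >= 1L && r <= bb$height && c >= 1L && c <= bb$width && inside[r, c]
  }
  grow <- function(pts) {
    n <- nrow(pts)
    k <- min(6L, n)
    dir <- pts[1, ] - pts[k, ]
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-9) return(pts)
    dir <- dir / nrm
    new_pts <- NULL
    pos <- pts[1, ]
    last <- round(pts[1, ])
    repeat {
      cand <- pos + 0.5 * dir
      cr <- round(cand)
      if (!in_blob(cand[1], cand[2])) break
      if (any(cr != last)) {
        new_pts <- rbind(cr, new_pts)
        last <- cr
      }
      pos <- cand
      if (!is.null(new_pts) && nrow(new_pts) > 1000L) break
    }
    if (is.null(new_pts)) pts else rbind(new_pts, pts)
  }
  pts <- grow(path$points)
  pts <- grow(pts[nrow(pts):1, , drop = FALSE])
  pts <- pts[nrow(pts):1, , drop = FALSE]
  colnames(pts) <- c("x", "y")
  rownames(pts) <- NULL
  structure(list(points = pts,
                 arc_length_px = sum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2))),
            class = "skeleton_path")
}

#' Equidistant points along a path
#'
#' Re-parameterizes a polyline by cumulative arc length and returns `k`
#' points at arc fractions `i/(k-1)`, `i = 0..k-1`, linearly interpolated
#' between vertices (subpixel output). For `k = 4` these are the four
#' points A, B, C, D dividing the dorsal into three segments of equal
#' length (A = head end, D = end of the caudal peduncle).
#'
#' @param path A `"skeleton_path"` or an `n x 2` point matrix (head first).
#' @param k Number of points (>= 2), default 4.
#' @return A `k x 2` matrix of (x, y) coordinates; rows named
#'   `A`, `B`, `C`, `D` when `k = 4`.
#' @export
equidistant_points <- function(path, k = 4L) {
  if (k < 2L) stop_gaitkin("k must be >= 2", "gaitkin_bad_input")
  pts <- if (inherits(path, "skeleton_path")) path$points else as.matrix(path)
  if (nrow(pts) < 2L)
    stop_gaitkin("path must have at least 2 points", "gaitkin_bad_input")
  cl <- polyline_cumlen(pts)
  total <- cl[length(cl)]
  if (total <= 0)
    stop_gaitkin("path has zero arc length", "gaitkin_bad_input")
  targets <- total * (seq_len(k) - 1) / (k - 1)
  out <- matrix(0, k, 2)
  seg <- pmin(pmax(findInterval(targets, cl, rightmost.closed = TRUE), 1L),
              nrow(pts) - 1L)
  for (i in seq_len(k)) {
    j <- seg[i]
    denom <- cl[j + 1L] - cl[j]
    f <- if (denom > 0) (targets[i] - cl[j]) / denom else 0
    out[i, ] <- pts[j, ] + f * (pts[j + 1L, ] - pts[j, ])
  }
  colnames(out) <- c("x", "y")
  if (k == 4L) rownames(out) <- c("A", "B", "C", "D")
  out
}
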