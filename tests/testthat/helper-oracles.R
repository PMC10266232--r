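# Independent oracles and small fixture builders used across the suite.

# Central finite-difference curvature of a curve function f(t) -> c(u, z).
fd_curvature <- function(f, t, h = 1e-5) {
  p_m <- unname(f(t - h)); p0 <- unname(f(t)); p_p <- unname(f(t + h))
  d1 <- (p_p - p_m) / (2 * h)
  d2 <- (p_p - 2 * p0 + p_m) / h^2
  abs(d1[1] * d2[2] - d2[1] * d1[2]) / sum(d1^2)^1.5
}

# Brute-force Otsu: maximize between-class variance over all 256 candidate
# integer levels of a [0, 255] grayscale matrix (class split: <= T vs > T).
otsu_bruteforce <- function(gray) {
  v <- as.numeric(gray)
  n <- length(v)
  best <- -Inf; best_t <- NA
  for (T in 0:254) {
    lo <- v[v <= T]; hi <- v[v > T]
    if (!length(lo) || !length(hi)) next
    wb <- length(lo) / n; wf <- 1 - wb
    bcv <- wb * wf * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_t <- T }
  }
  best_t
}

# Exhaustive optimal bipartite matching: maximum number of pred-gt pairs with
# IoU >= threshold, each side used at most once (small n only).
match_bruteforce <- function(preds, gts, iou_threshold) {
  np <- nrow(preds); ng <- nrow(gts)
  M <- outer(seq_len(np), seq_len(ng), Vectorize(function(i, j)
    box_iou(unlist(preds[i, c("xmin", "ymin", "xmax", "ymax")]),
            unlist(gts[j, c("xmin", "ymin", "xmax", "ymax")]))))
  ok <- M >= iou_threshold
  best <- 0L
  recurse <- function(i, used) {
    if (i > np) return(0L)
    top <- recurse(i + 1L, used)            # leave pred i unmatched
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      top <- max(top, 1L + recurse(i + 1L, used))
      used[j] <- FALSE
    }
    top
  }
  if (ng == 0L) 0L else recurse(1L, rep(FALSE, ng))
}

# Point-in-convex-hull test with slack (mm).
in_hull <- function(pts, hull_pts, tol = 1e-9) {
  h <- grDevices::chull(hull_pts)
  hull <- hull_pts[h, , drop = FALSE]
  n <- nrow(hull)
  if (n < 3) {
    # degenerate hull: check distance to the segment/point
    a <- hull[1, ]; b <- hull[min(2, n), ]
    ab <- b - a
    apply(pts, 1, function(p) {
      tt <- if (sum(ab^2) < 1e-300) 0 else
        max(0, min(1, sum((p - a) * ab) / sum(ab^2)))
      sqrt(sum((a + tt * ab - p)^2)) <= tol
    })
  } else {
    # chull returns vertices clockwise; inside = all cross products <= tol
    apply(pts, 1, function(p) {
      all(vapply(seq_len(n), function(i) {
        a <- hull[i, ]; b <- hull[i %% n + 1, ]
        (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
      }, numeric(1)) <= tol * max(1, max(abs(hull))))
    })
  }
}

# A random cubic Bezier segment with coordinates in [-r, r].
random_segment <- function(r = 100) {
  bezier_segment(stats::runif(2, -r, r), stats::runif(2, -r, r),
                 stats::runif(2, -r, r), stats::runif(2, -r, r))
}

# Binary mask with rectangular blobs; blobs = list of c(row0, col0, h, w),
# 1-based inclusive origin.
rect_mask <- function(nrow, ncol, blobs) {
  m <- matrix(0L, nrow, ncol)
  for (b in blobs)
    m[b[1]:(b[1] + b[3] - 1), b[2]:(b[2] + b[4] - 1)] <- 1L
  m
}
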