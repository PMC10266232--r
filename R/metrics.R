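# Box-level detection evaluation: IoU, confidence-ranked greedy matching,
# precision / recall and interpolated average precision. Boxes are half-open
# pixel rectangles [xmin, xmax) x [ymin, ymax), 0-based.

#' Read YOLO-format labels
#'
#' Each line is \code{class cx cy w h [confidence]} with centre/size
#' normalized to [0, 1]; coordinates are converted to half-open pixel boxes.
#'
#' @param path label text file (may be empty or absent: zero boxes).
#' @param width,height image size in pixels.
#' @return data.frame with class, xmin, ymin, xmax, ymax and conf (NA when
#'   the file carries no confidence column).
#' @export
read_yolo_labels <- function(path, width, height) {
  empty <- data.frame(class = integer(), xmin = numeric(), ymin = numeric(),
                      xmax = numeric(), ymax = numeric(), conf = numeric())
  if (!file.exists(path)) return(empty)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  f <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(v) {
    v <- as.numeric(v)
    c(v[1:5], if (length(v) >= 6) v[6] else NA_real_)
  }))
  data.frame(class = as.integer(f[, 1]),
             xmin = (f[, 2] - f[, 4] / 2) * width,
             ymin = (f[, 3] - f[, 5] / 2) * height,
             xmax = (f[, 2] + f[, 4] / 2) * width,
             ymax = (f[, 3] + f[, 5] / 2) * height,
             conf = f[, 6])
}

#' Write YOLO-format labels
#'
#' @param boxes data.frame with xmin, ymin, xmax, ymax (pixels) and
#'   optionally class and conf columns.
#' @param path output text file.
#' @param width,height image size in pixels.
#' @export
write_yolo_labels <- function(boxes, path, width, height) {
  cls <- boxes$class %||% rep(0L, nrow(boxes))
  cx <- (boxes$xmin + boxes$xmax) / 2 / width
  cy <- (boxes$ymin + boxes$ymax) / 2 / height
  w <- (boxes$xmax - boxes$xmin) / width
  h <- (boxes$ymax - boxes$ymin) / height
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", cls, cx, cy, w, h)
  if (!is.null(boxes$conf) && !all(is.na(boxes$conf)))
    lines <- paste(lines, sprintf("%.6f", boxes$conf))
  writeLines(lines, path)
  invisible(path)
}

#' Intersection over union of two boxes
#'
#' |A intersect B| / |A union B| for half-open rectangles.
#'
#' @param a,b length-4 vectors (xmin, ymin, xmax, ymax).
#' @return IoU in [0, 1]; a zero-area box gives 0 with a warning.
#' @export
box_iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  area_a <- max(0, a[3] - a[1]) * max(0, a[4] - a[2])
  area_b <- max(0, b[3] - b[1]) * max(0, b[4] - b[2])
  if (area_a == 0 || area_b == 0) {
    warning("zero-area box in IoU; returning 0")
    return(0)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (area_a + area_b - inter)
}

iou_matrix <- function(preds, gts) {
  np <- nrow(preds); ng <- nrow(gts)
  iw <- outer(preds$xmax, gts$xmax, pmin) - outer(preds$xmin, gts$xmin, pmax)
  ih <- outer(preds$ymax, gts$ymax, pmin) - outer(preds$ymin, gts$ymin, pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  area_p <- (preds$xmax - preds$xmin) * (preds$ymax - preds$ymin)
  area_g <- (gts$xmax - gts$xmin) * (gts$ymax - gts$ymin)
  un <- outer(area_p, area_g, `+`) - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}

#' Greedy matching of predictions to ground truth
#'
#' Predictions are visited in descending confidence; each is assigned to the
#' still-unmatched ground-truth box of highest IoU, provided that IoU reaches
#' the threshold. Unassigned predictions are false positives, unassigned
#' ground-truth boxes false negatives.
#'
#' @param preds data.frame of predicted boxes with a conf column.
#' @param gts data.frame of ground-truth boxes.
#' @param iou_threshold matching threshold.
#' @return an object of class \code{match_counts}: tp, fp, fn plus the
#'   per-prediction match table (pred row, gt row or NA, iou).
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  np <- if (is.null(preds)) 0L else nrow(preds)
  ng <- if (is.null(gts)) 0L else nrow(gts)
  if (np == 0L) {
    return(structure(list(tp = 0L, fp = 0L, fn = ng,
                          matches = data.frame(pred = integer(), gt = integer(),
                                               iou = numeric())),
                     class = "match_counts"))
  }
  ord <- order(-(preds$conf %||% rep(1, np)))
  M <- if (ng) iou_matrix(preds, gts) else matrix(0, np, 0)
  gt_used <- rep(FALSE, ng)
  match_gt <- rep(NA_integer_, np)
  match_iou <- rep(NA_real_, np)
  for (i in ord) {
    if (!ng) break
    cand <- which(!gt_used & M[i, ] >= iou_threshold)
    if (length(cand)) {
      j <- cand[which.max(M[i, cand])]
      gt_used[j] <- TRUE
      match_gt[i] <- j
      match_iou[i] <- M[i, j]
    }
  }
  tp <- sum(!is.na(match_gt))
  structure(list(tp = tp, fp = np - tp, fn = ng - tp,
                 matches = data.frame(pred = seq_len(np), gt = match_gt,
                                      iou = match_iou)),
            class = "match_counts")
}

#' Tally container for detection matching
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return an object of class \code{match_counts}.
#' @export
match_counts <- function(tp, fp, fn) {
  v <- c(tp = tp, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v)))
    stop("tp, fp, fn must be non-negative integers", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn)),
            class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("Detections: TP = %d, FP = %d, FN = %d\n", x$tp, x$fp, x$fn))
  p <- tryCatch(precision_pct(x), warning = function(w) NA_real_)
  r <- tryCatch(recall_pct(x), warning = function(w) NA_real_)
  cat(sprintf("  precision = %s%%, recall = %s%%\n",
              if (is.na(p)) "NA" else sprintf("%.1f", round_half_up(p, 1)),
              if (is.na(r)) "NA" else sprintf("%.1f", round_half_up(r, 1))))
  invisible(x)
}

#' Precision and recall (percent)
#'
#' precision = 100 TP / (TP + FP); recall = 100 TP / (TP + FN).
#'
#' @param counts a \code{\link{match_counts}}.
#' @return percentage in [0, 100]; NA with a warning when the denominator is
#'   zero (no predictions / no ground truth).
#' @export
precision_pct <- function(counts) {
  stopifnot(inherits(counts, "match_counts"))
  den <- counts$tp + counts$fp
  if (den == 0) {
    warning("precision undefined: no predictions (TP + FP = 0)")
    return(NA_real_)
  }
  100 * counts$tp / den
}

#' @rdname precision_pct
#' @export
recall_pct <- function(counts) {
  stopifnot(inherits(counts, "match_counts"))
  den <- counts$tp + counts$fn
  if (den == 0) {
    warning("recall undefined: no ground truth (TP + FN = 0)")
    return(NA_real_)
  }
  100 * counts$tp / den
}

#' Average precision at one IoU threshold
#'
#' Predictions are ranked by confidence; true/false-positive flags follow the
#' greedy matching protocol. AP is the area under the monotone (all-point
#' interpolated) precision-recall envelope, in percent.
#'
#' @inheritParams match_detections
#' @return AP in [0, 100]; NA with a warning when there is no ground truth.
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5) {
  ng <- if (is.null(gts)) 0L else nrow(gts)
  if (ng == 0L) {
    warning("average precision undefined: no ground truth")
    return(NA_real_)
  }
  np <- if (is.null(preds)) 0L else nrow(preds)
  if (np == 0L) return(0)
  res <- match_detections(preds, gts, iou_threshold)
  ord <- order(-(preds$conf %||% rep(1, np)))
  is_tp <- !is.na(res$matches$gt[ord])
  cum_tp <- cumsum(is_tp)
  prec <- cum_tp / seq_len(np)
  rec <- cum_tp / ng
  # monotone envelope from the right, then sum rectangle areas at recall steps
  prec_env <- rev(cummax(rev(prec)))
  recall_prev <- c(0, rec[-np])
  100 * sum((rec - recall_prev) * prec_env)
}

#' Mean average precision over IoU thresholds
#'
#' @inheritParams match_detections
#' @param thresholds IoU thresholds; the default 0.5, 0.55, ..., 0.95 is the
#'   usual strict sweep, \code{thresholds = 0.5} the lenient single-threshold
#'   variant.
#' @return mean AP in [0, 100].
#' @export
mean_average_precision <- function(preds, gts,
                                   thresholds = seq(0.5, 0.95, by = 0.05)) {
  mean(vapply(thresholds, function(th) average_precision(preds, gts, th),
              numeric(1)))
}

#' Evaluate a directory pair of YOLO labels
#'
#' Matches per-image prediction and ground-truth label files by name and
#' aggregates counts over the set.
#'
#' @param pred_dir,gt_dir directories of YOLO label files; predictions carry
#'   a 6th confidence column.
#' @param width,height image size the normalized labels refer to.
#' @param iou_threshold matching threshold.
#' @return list with the pooled \code{counts} (\code{match_counts}),
#'   \code{precision}, \code{recall} (percent) and a per-image data.frame.
#' @export
evaluate_label_dirs <- function(pred_dir, gt_dir, width, height,
                                iou_threshold = 0.5) {
  files <- sort(unique(c(list.files(pred_dir, "\\.txt$"),
                         list.files(gt_dir, "\\.txt$"))))
  per <- do.call(rbind, lapply(files, function(f) {
    p <- read_yolo_labels(file.path(pred_dir, f), width, height)
    g <- read_yolo_labels(file.path(gt_dir, f), width, height)
    m <- match_detections(p, g, iou_threshold)
    data.frame(image = f, tp = m$tp, fp = m$fp, fn = m$fn)
  }))
  counts <- match_counts(sum(per$tp), sum(per$fp), sum(per$fn))
  list(counts = counts,
       precision = precision_pct(counts),
       recall = recall_pct(counts),
       per_image = per)
}
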