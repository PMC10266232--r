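# Excess-green weed segmentation: 2G - R - B, Otsu binarization, opening,
# connected-domain area filtering, centroid / outer-rectangle extraction.
# Images are numeric height x width x 3 arrays with 8-bit channel values in
# [0, 255], row-major with the origin at the top-left pixel; reported pixel
# coordinates are 0-based (x = column, y = row).

#' Read an RGB image from PNG
#'
#' @param path PNG file.
#' @return height x width x 3 numeric array, channel values in [0, 255].
#' @export
read_image_rgb <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  a[, , 1:3, drop = FALSE] * 255
}

#' Write an RGB image to PNG
#'
#' @param img height x width x 3 array in [0, 255].
#' @param path output file.
#' @export
write_image_rgb <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

#' Segmentation configuration
#'
#' @param mcds minimum connected domain size: smallest component pixel area
#'   retained as a weed.
#' @param kernel odd morphological kernel size (cross-shaped).
#' @param erode_iter,dilate_iter opening iterations.
#' @param rect_mode outer-rectangle mode: axis-aligned bounding box
#'   (\code{"axis"}) or minimum-area rotated rectangle (\code{"rotated"}).
#' @param clip_negative if TRUE, negative excess-green values are clipped to 0
#'   before min-max normalization.
#' @param exg_floor absolute excess-green floor: pixels whose raw 2G - R - B
#'   does not exceed this are never foreground. Guards the per-image Otsu
#'   split against vegetation-free images, where it would otherwise bisect
#'   pure soil noise.
#' @return an object of class \code{seg_config}.
#' @export
seg_config <- function(mcds = 50, kernel = 3, erode_iter = 1, dilate_iter = 1,
                       rect_mode = c("axis", "rotated"), clip_negative = FALSE,
                       exg_floor = 20) {
  mcds <- as.integer(mcds); kernel <- as.integer(kernel)
  if (mcds < 1L) stop("mcds must be >= 1", call. = FALSE)
  if (kernel %% 2L != 1L || kernel < 1L) stop("kernel size must be odd", call. = FALSE)
  structure(list(mcds = mcds, kernel = kernel,
                 erode_iter = as.integer(erode_iter),
                 dilate_iter = as.integer(dilate_iter),
                 rect_mode = match.arg(rect_mode),
                 clip_negative = isTRUE(clip_negative),
                 exg_floor = exg_floor),
            class = "seg_config")
}

check_rgb <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("image must be a height x width x 3 array", call. = FALSE)
  invisible(img)
}

#' Excess-green vegetation index map
#'
#' Per pixel 2G - R - B, the classic index separating green foliage from soil;
#' values span [-510, 510].
#'
#' @param img height x width x 3 array in [0, 255].
#' @return height x width signed matrix.
#' @export
exg_map <- function(img) {
  check_rgb(img)
  2 * img[, , 2] - img[, , 1] - img[, , 3]
}

#' Otsu binarization of an excess-green map
#'
#' The signed map is min-max normalized to [0, 255] (optionally clipping
#' negatives first), then thresholded at the gray level maximizing
#' between-class variance; foreground is the above-threshold class.
#'
#' @param map signed excess-green matrix.
#' @param clip_negative clip negative values to 0 before normalizing.
#' @param min_value absolute floor on the raw map: pixels at or below it are
#'   forced to background regardless of the threshold (\code{-Inf} disables).
#' @return integer 0/1 foreground matrix with attribute \code{threshold}
#'   (gray level in [0, 255] on the normalized scale). A constant map yields
#'   an empty mask with a warning.
#' @export
otsu_binarize <- function(map, clip_negative = FALSE, min_value = -Inf) {
  if (!is.matrix(map)) stop("map must be a matrix", call. = FALSE)
  raw <- map
  if (clip_negative) map <- pmax(map, 0)
  rng <- range(map)
  if (diff(rng) < .Machine$double.eps) {
    warning("constant excess-green map: empty foreground")
    out <- matrix(0L, nrow(map), ncol(map))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  norm <- (map - rng[1]) / diff(rng) * 255
  thr <- EBImage::otsu(EBImage::Image(norm / 255), range = c(0, 1),
                       levels = 256) * 255
  out <- matrix(0L, nrow(map), ncol(map))
  out[norm > thr & raw > min_value] <- 1L
  attr(out, "threshold") <- thr
  out
}

#' Morphological opening of a binary mask
#'
#' Erosion then dilation with a cross-shaped kernel: removes specks smaller
#' than the kernel while approximately preserving large blobs.
#'
#' @param mask integer 0/1 matrix.
#' @param kernel odd kernel size.
#' @param erode_iter,dilate_iter iteration counts.
#' @return integer 0/1 matrix.
#' @export
morph_refine <- function(mask, kernel = 3, erode_iter = 1, dilate_iter = 1) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  kern <- EBImage::makeBrush(as.integer(kernel), shape = "diamond")
  m <- mask
  for (i in seq_len(erode_iter)) m <- EBImage::erode(m, kern)
  for (i in seq_len(dilate_iter)) m <- EBImage::dilate(m, kern)
  out <- matrix(as.integer(m > 0), nrow(mask), ncol(mask))
  out
}

# 8-connectivity labelling: EBImage's 4-connected labelling, then union-find
# merging of labels that touch diagonally.
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 4 || nlab <= 1L) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))    # up-right
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

#' Connected-domain filtering of a binary mask
#'
#' Labels the mask's connected components (8-connectivity) and retains those
#' whose pixel area is at least the minimum connected domain size.
#'
#' @param mask integer 0/1 matrix.
#' @param mcds minimum retained component area (inclusive).
#' @param connectivity 8 (default) or 4.
#' @return an object of class \code{component_set}: \code{labels} (matrix,
#'   0 = background, retained components relabelled 1..k) and \code{stats}
#'   (data.frame: id, area, centroid_x, centroid_y (0-based pixel
#'   coordinates), xmin, ymin, xmax, ymax (half-open pixel box)), ordered by
#'   the (row, column) of each component's top-left pixel.
#' @export
filter_components <- function(mask, mcds = 50, connectivity = 8) {
  lab <- label_components(mask, connectivity)
  nlab <- max(lab)
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(mask), ncol(mask)),
                   stats = data.frame(id = integer(), area = integer(),
                                      centroid_x = numeric(), centroid_y = numeric(),
                                      xmin = integer(), ymin = integer(),
                                      xmax = integer(), ymax = integer()),
                   mcds = as.integer(mcds)),
              class = "component_set")
  }
  if (nlab == 0L) return(empty())
  idx <- which(lab > 0L)
  ids <- lab[idx]
  row0 <- (idx - 1L) %% nrow(lab)        # 0-based row (y)
  col0 <- (idx - 1L) %/% nrow(lab)       # 0-based col (x)
  area <- tabulate(ids, nlab)
  keep <- which(area >= mcds)
  if (!length(keep)) return(empty())
  st <- data.frame(
    id = seq_along(keep),
    area = area[keep],
    centroid_x = vapply(keep, function(k) mean(col0[ids == k]), numeric(1)),
    centroid_y = vapply(keep, function(k) mean(row0[ids == k]), numeric(1)),
    xmin = vapply(keep, function(k) min(col0[ids == k]), numeric(1)),
    ymin = vapply(keep, function(k) min(row0[ids == k]), numeric(1)),
    xmax = vapply(keep, function(k) max(col0[ids == k]) + 1, numeric(1)),
    ymax = vapply(keep, function(k) max(row0[ids == k]) + 1, numeric(1))
  )
  ord <- order(st$ymin, st$xmin, st$id)
  st <- st[ord, ]
  st$id <- seq_len(nrow(st))
  rownames(st) <- NULL
  relab <- integer(nlab)
  relab[keep[ord]] <- st$id
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[idx] <- relab[ids]
  structure(list(labels = out, stats = st, mcds = as.integer(mcds)),
            class = "component_set")
}

#' @export
print.component_set <- function(x, ...) {
  cat(sprintf("Component set: %d components with area >= %d px\n",
              nrow(x$stats), x$mcds))
  if (nrow(x$stats)) print(utils::head(x$stats, 10))
  invisible(x)
}

# Minimum-area enclosing rectangle of a point set via rotating the hull edges.
min_area_rect <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) == 1L)
    return(list(cx = xy[1, 1], cy = xy[1, 2], width = 0, height = 0, angle = 0))
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  edges <- diff(rbind(hull, hull[1, , drop = FALSE]))
  angles <- unique(atan2(edges[, 2], edges[, 1]) %% (pi / 2))
  best <- NULL
  for (a in angles) {
    rot <- cbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    r <- hull %*% rot
    w <- diff(range(r[, 1])); hgt <- diff(range(r[, 2]))
    if (is.null(best) || w * hgt < best$area) {
      ctr <- c(mean(range(r[, 1])), mean(range(r[, 2]))) %*% t(rot)
      best <- list(area = w * hgt, cx = ctr[1], cy = ctr[2],
                   width = w, height = hgt, angle = a)
    }
  }
  best[c("cx", "cy", "width", "height", "angle")]
}

#' Extract weed descriptors from filtered components
#'
#' Each retained connected domain becomes one weed: its morphological centre
#' (mean pixel coordinate) and its outer rectangle, axis-aligned by default or
#' the minimum-area rotated rectangle.
#'
#' @param components a \code{\link{filter_components}} result.
#' @param rect_mode \code{"axis"} or \code{"rotated"}.
#' @return data.frame with id, area, centroid_x, centroid_y, xmin, ymin,
#'   xmax, ymax and, for rotated mode, rect_cx, rect_cy, rect_w, rect_h,
#'   rect_angle (radians).
#' @export
extract_weeds <- function(components, rect_mode = c("axis", "rotated")) {
  stopifnot(inherits(components, "component_set"))
  rect_mode <- match.arg(rect_mode)
  st <- components$stats
  if (rect_mode == "rotated" && nrow(st)) {
    lab <- components$labels
    rects <- lapply(st$id, function(k) {
      idx <- which(lab == k)
      xy <- cbind((idx - 1L) %/% nrow(lab), (idx - 1L) %% nrow(lab))
      min_area_rect(xy)
    })
    st$rect_cx <- vapply(rects, `[[`, numeric(1), "cx")
    st$rect_cy <- vapply(rects, `[[`, numeric(1), "cy")
    st$rect_w <- vapply(rects, `[[`, numeric(1), "width")
    st$rect_h <- vapply(rects, `[[`, numeric(1), "height")
    st$rect_angle <- vapply(rects, `[[`, numeric(1), "angle")
  }
  st
}

#' Blank out crop boxes in an image
#'
#' Pixels inside the supplied crop bounding boxes are set to black so crop
#' foliage cannot enter the weed mask; global pixel coordinates are preserved.
#'
#' @param img height x width x 3 array.
#' @param boxes data.frame with half-open 0-based pixel columns xmin, ymin,
#'   xmax, ymax (clipped to the image); NULL or empty leaves the image
#'   untouched.
#' @return the masked image.
#' @export
mask_crops <- function(img, boxes) {
  check_rgb(img)
  if (is.null(boxes) || nrow(boxes) == 0L) return(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  for (i in seq_len(nrow(boxes))) {
    x0 <- max(0, floor(boxes$xmin[i])); x1 <- min(w, ceiling(boxes$xmax[i]))
    y0 <- max(0, floor(boxes$ymin[i])); y1 <- min(h, ceiling(boxes$ymax[i]))
    if (x1 > x0 && y1 > y0)
      img[(y0 + 1):y1, (x0 + 1):x1, ] <- 0
  }
  img
}

#' Camera calibration
#'
#' Affine pixel-to-robot-frame map: scale by \code{mm_per_px}, then add the
#' fixed camera-origin offset and the robot's advance offset along x (the
#' machine drives a fixed distance so the arm workspace lands over the imaged
#' patch).
#'
#' @param mm_per_px millimetres per pixel.
#' @param camera_origin_mm length-2 robot-frame position of pixel (0, 0).
#' @param advance_offset_mm fixed camera-to-arm advance along x (mm).
#' @return an object of class \code{camera_calib}.
#' @export
camera_calib <- function(mm_per_px = 1, camera_origin_mm = c(0, 0),
                         advance_offset_mm = 0) {
  stop_if_not_scalar(mm_per_px, "mm_per_px")
  if (mm_per_px <= 0) stop("mm_per_px must be positive", call. = FALSE)
  structure(list(mm_per_px = mm_per_px,
                 camera_origin_mm = as.numeric(camera_origin_mm),
                 advance_offset_mm = advance_offset_mm),
            class = "camera_calib")
}

#' Map pixel coordinates to robot-frame millimetres
#'
#' @param pt length-2 (x, y) pixel coordinates, or an n x 2 matrix.
#' @param calib a \code{\link{camera_calib}}.
#' @return n x 3 matrix of robot-frame (x, y, z = 0) points in mm.
#' @export
pixel_to_robot <- function(pt, calib) {
  if (!inherits(calib, "camera_calib"))
    stop("calibration must be a camera_calib object", call. = FALSE)
  pt <- matrix(as.numeric(pt), ncol = 2)
  cbind(x = pt[, 1] * calib$mm_per_px + calib$camera_origin_mm[1] +
          calib$advance_offset_mm,
        y = pt[, 2] * calib$mm_per_px + calib$camera_origin_mm[2],
        z = 0)
}

#' Inverse of \code{\link{pixel_to_robot}}
#'
#' @param pt length-2/3 robot-frame mm point or n x 2/3 matrix (z ignored).
#' @param calib a \code{\link{camera_calib}}.
#' @return n x 2 matrix of pixel coordinates.
#' @export
robot_to_pixel <- function(pt, calib) {
  if (!inherits(calib, "camera_calib"))
    stop("calibration must be a camera_calib object", call. = FALSE)
  pt <- as.matrix(pt)
  if (ncol(pt) == 1L) pt <- t(pt)
  cbind(x = (pt[, 1] - calib$camera_origin_mm[1] - calib$advance_offset_mm) /
          calib$mm_per_px,
        y = (pt[, 2] - calib$camera_origin_mm[2]) / calib$mm_per_px)
}

#' Full weed-segmentation chain
#'
#' Blanks the crop boxes, computes the excess-green map, Otsu-binarizes it,
#' applies morphological opening and connected-domain filtering, and extracts
#' weed centroids and outer rectangles.
#'
#' @param img height x width x 3 array in [0, 255].
#' @param crop_boxes optional data.frame of crop pixel boxes (xmin, ymin,
#'   xmax, ymax).
#' @param cfg a \code{\link{seg_config}}.
#' @return an object of class \code{weed_segmentation}: \code{weeds}
#'   (data.frame as in \code{\link{extract_weeds}}), \code{components},
#'   \code{mask} (post-morphology), \code{threshold} and the \code{config}.
#' @export
segment_weeds <- function(img, crop_boxes = NULL, cfg = seg_config()) {
  stopifnot(inherits(cfg, "seg_config"))
  masked <- mask_crops(img, crop_boxes)
  exg <- exg_map(masked)
  bin <- otsu_binarize(exg, clip_negative = cfg$clip_negative,
                       min_value = cfg$exg_floor)
  thr <- attr(bin, "threshold")
  refined <- morph_refine(bin, cfg$kernel, cfg$erode_iter, cfg$dilate_iter)
  comp <- filter_components(refined, cfg$mcds)
  weeds <- extract_weeds(comp, cfg$rect_mode)
  structure(list(weeds = weeds, components = comp, mask = refined,
                 threshold = thr, config = cfg, crop_boxes = crop_boxes),
            class = "weed_segmentation")
}

#' @export
print.weed_segmentation <- function(x, ...) {
  cat(sprintf("Weed segmentation: %d weeds (mcds = %d, Otsu threshold %.1f)\n",
              nrow(x$weeds), x$config$mcds,
              if (is.na(x$threshold)) NA_real_ else x$threshold))
  if (nrow(x$weeds)) print(utils::head(x$weeds, 10))
  invisible(x)
}
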