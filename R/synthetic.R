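# Seeded generators for ground-truthed fixtures: field-like RGB images (soil
# background, irregular green weed blobs, larger crop plants with known
# boxes), 3-D spray scenes, and detection tables with prescribed TP/FP/FN.
# Ground truth is recorded exactly as drawn, never re-measured from the image.

#' Field image scene configuration
#'
#' @param width,height image size (pixels).
#' @param n_weeds number of weed blobs.
#' @param weed_area_px length-2 range of weed blob areas (pixels).
#' @param n_crops number of crop plants (drawn larger than weeds).
#' @param crop_diameter_px length-2 range of crop blob diameters (pixels).
#' @param soil_rgb soil base colour (R, G, B in [0, 255]); brown-dominant.
#' @param noise per-channel uniform pixel noise amplitude.
#' @param min_exg_contrast minimum excess-green contrast of vegetation over
#'   the soil median.
#' @param seed RNG seed.
#' @return an object of class \code{field_scene_config}.
#' @export
field_scene_config <- function(width = 640, height = 640, n_weeds = 30,
                               weed_area_px = c(100, 900), n_crops = 3,
                               crop_diameter_px = c(60, 100),
                               soil_rgb = c(120, 95, 70), noise = 10,
                               min_exg_contrast = 60, seed = NULL) {
  stopifnot(width >= 32, height >= 32, n_weeds >= 0, n_crops >= 0,
            length(weed_area_px) == 2, weed_area_px[1] >= 1,
            diff(weed_area_px) >= 0, noise >= 0, min_exg_contrast >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_weeds = as.integer(n_weeds),
                 weed_area_px = as.numeric(weed_area_px),
                 n_crops = as.integer(n_crops),
                 crop_diameter_px = as.numeric(crop_diameter_px),
                 soil_rgb = as.numeric(soil_rgb), noise = noise,
                 min_exg_contrast = min_exg_contrast, seed = seed),
            class = "field_scene_config")
}

# Rasterize one irregular blob: ellipse-like region whose radius is perturbed
# by low-order angular harmonics. Returns 1-based (row, col) pixel indices.
blob_pixels <- function(cx, cy, r0, aspect, irregularity, width, height) {
  nh <- 3
  amp <- stats::runif(nh, 0, irregularity / nh)
  pha <- stats::runif(nh, 0, 2 * pi)
  rot <- stats::runif(1, 0, pi)
  rmax <- r0 * (1 + sum(amp)) * max(aspect, 1 / aspect) + 2
  x0 <- max(1, floor(cx - rmax)); x1 <- min(width, ceiling(cx + rmax))
  y0 <- max(1, floor(cy - rmax)); y1 <- min(height, ceiling(cy + rmax))
  if (x1 < x0 || y1 < y0) return(cbind(row = integer(), col = integer()))
  gx <- x0:x1; gy <- y0:y1
  dx <- outer(rep(1, length(gy)), gx - cx)
  dy <- outer(gy - cy, rep(1, length(gx)))
  # rotate, then squeeze one axis for ellipticity
  rx <- dx * cos(rot) + dy * sin(rot)
  ry <- -dx * sin(rot) + dy * cos(rot)
  rx <- rx / aspect
  ry <- ry * aspect
  th <- atan2(ry, rx)
  rad <- sqrt(rx^2 + ry^2)
  redge <- r0 * (1 + Reduce(`+`, lapply(seq_len(nh), function(k)
    amp[k] * cos(k * th + pha[k]))))
  inside <- rad <= redge
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = gy[idx[, 1]], col = gx[idx[, 2]])
}

# Draw a blob with rasterized area close to target_area, inside the free mask
# (TRUE = free). Returns pixels or NULL when the spot is occupied.
place_blob <- function(free, target_area, aspect, irregularity, margin) {
  h <- nrow(free); w <- ncol(free)
  r0 <- sqrt(target_area / pi)
  cx <- stats::runif(1, r0 + margin + 1, w - r0 - margin - 1)
  cy <- stats::runif(1, r0 + margin + 1, h - r0 - margin - 1)
  px <- blob_pixels(cx, cy, r0, aspect, irregularity, w, h)
  for (rescale in 1:4) {
    if (nrow(px) == 0) return(NULL)
    ratio <- target_area / nrow(px)
    if (abs(ratio - 1) < 0.08) break
    r0 <- r0 * sqrt(ratio)
    px <- blob_pixels(cx, cy, r0, aspect, irregularity, w, h)
  }
  if (nrow(px) == 0) return(NULL)
  # occupancy check with a margin ring so neighbouring blobs never touch
  rr <- px[, 1]; cc <- px[, 2]
  for (dr in -margin:margin) for (dc in -margin:margin) {
    r2 <- clamp(rr + dr, 1, h); c2 <- clamp(cc + dc, 1, w)
    if (any(!free[cbind(r2, c2)])) return(NULL)
  }
  px
}

#' Generate a ground-truthed synthetic field image
#'
#' Renders a soil-coloured background with per-pixel uniform noise, then
#' places non-overlapping irregular green weed blobs and larger crop plants.
#' Vegetation colours are chosen so every vegetation pixel keeps at least the
#' configured excess-green contrast over the soil median even under the noise.
#' The ground truth (areas, centroids, boxes) comes from the drawn pixel sets.
#'
#' @param cfg a \code{\link{field_scene_config}}.
#' @return an object of class \code{field_scene}: \code{image} (height x
#'   width x 3, [0, 255]), \code{weeds} (data.frame: id, area, centroid_x,
#'   centroid_y, xmin, ymin, xmax, ymax; 0-based pixel coordinates, half-open
#'   boxes), \code{crop_boxes} (same box columns) and the \code{config}.
#'   Placement failure after bounded retries is an error.
#' @export
gen_field_image <- function(cfg = field_scene_config()) {
  stopifnot(inherits(cfg, "field_scene_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  h <- cfg$height; w <- cfg$width
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- clamp(cfg$soil_rgb[ch] +
                           stats::runif(h * w, -cfg$noise, cfg$noise), 0, 255)

  soil_exg_med <- 2 * cfg$soil_rgb[2] - cfg$soil_rgb[1] - cfg$soil_rgb[3]
  # worst-case noise swing of the ExG of a single pixel is 4 * noise
  exg_floor <- soil_exg_med + cfg$min_exg_contrast + 4 * cfg$noise

  veg_color <- function() {
    r <- stats::runif(1, 40, 90)
    b <- stats::runif(1, 30, 80)
    g_min <- (exg_floor + r + b) / 2 + 2 * cfg$noise
    g <- stats::runif(1, max(120, g_min), max(200, g_min + 30))
    c(r, min(g, 255), b)
  }

  free <- matrix(TRUE, h, w)
  margin <- 3L
  paint <- function(px, col) {
    for (ch in 1:3)
      img[cbind(px[, 1], px[, 2], ch)] <<-
        clamp(col[ch] + stats::runif(nrow(px), -cfg$noise, cfg$noise), 0, 255)
    free[px] <<- FALSE
  }
  truth_row <- function(id, px) {
    data.frame(id = id, area = nrow(px),
               centroid_x = mean(px[, 2] - 1), centroid_y = mean(px[, 1] - 1),
               xmin = min(px[, 2]) - 1, ymin = min(px[, 1]) - 1,
               xmax = max(px[, 2]), ymax = max(px[, 1]))
  }

  crops <- list()
  for (i in seq_len(cfg$n_crops)) {
    ok <- FALSE
    for (try in 1:200) {
      d <- stats::runif(1, cfg$crop_diameter_px[1], cfg$crop_diameter_px[2])
      px <- place_blob(free, pi * (d / 2)^2, stats::runif(1, 0.8, 1.25), 0.25,
                       margin)
      if (!is.null(px)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place crop ", i, " without overlap", call. = FALSE)
    paint(px, veg_color())
    crops[[i]] <- truth_row(i, px)
  }

  weeds <- list()
  for (i in seq_len(cfg$n_weeds)) {
    ok <- FALSE
    for (try in 1:200) {
      a <- stats::runif(1, cfg$weed_area_px[1], cfg$weed_area_px[2])
      px <- place_blob(free, a, stats::runif(1, 0.7, 1.4), 0.3, margin)
      if (!is.null(px) && nrow(px) >= cfg$weed_area_px[1] &&
          nrow(px) <= cfg$weed_area_px[2] * 1.1) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place weed ", i, " without overlap", call. = FALSE)
    paint(px, veg_color())
    weeds[[i]] <- truth_row(i, px)
  }

  crop_boxes <- if (length(crops)) do.call(rbind, crops)[, -(1:4)] else
    data.frame(xmin = numeric(), ymin = numeric(),
               xmax = numeric(), ymax = numeric())
  # expand crop boxes a little so the masking removes boundary bleed
  if (nrow(crop_boxes)) {
    crop_boxes$xmin <- pmax(0, crop_boxes$xmin - 2)
    crop_boxes$ymin <- pmax(0, crop_boxes$ymin - 2)
    crop_boxes$xmax <- pmin(w, crop_boxes$xmax + 2)
    crop_boxes$ymax <- pmin(h, crop_boxes$ymax + 2)
  }
  structure(list(image = img,
                 weeds = if (length(weeds)) do.call(rbind, weeds) else
                   data.frame(id = integer(), area = integer(),
                              centroid_x = numeric(), centroid_y = numeric(),
                              xmin = numeric(), ymin = numeric(),
                              xmax = numeric(), ymax = numeric()),
                 crop_boxes = crop_boxes, config = cfg),
            class = "field_scene")
}

#' @export
print.field_scene <- function(x, ...) {
  cat(sprintf("Synthetic field scene: %d x %d px, %d weeds, %d crops\n",
              x$config$width, x$config$height, nrow(x$weeds),
              nrow(x$crop_boxes)))
  invisible(x)
}

#' Spray scene generator configuration
#'
#' @param dist_range weed-pair distance range (mm).
#' @param w1_range,w2_range,h3_range crop cylinder parameter ranges (mm).
#' @param h1,h2 trajectory phase heights (mm).
#' @param margin required clearance margin (mm).
#' @param samples trajectory polyline samples per phase.
#' @param seed RNG seed.
#' @return an object of class \code{spray_scene_config}.
#' @export
spray_scene_config <- function(dist_range = c(180, 320),
                               w1_range = c(40, 80), w2_range = c(20, 45),
                               h3_range = c(100, 160), h1 = 20, h2 = 150,
                               margin = 0, samples = 200, seed = NULL) {
  structure(list(dist_range = as.numeric(dist_range),
                 w1_range = as.numeric(w1_range),
                 w2_range = as.numeric(w2_range),
                 h3_range = as.numeric(h3_range),
                 h1 = h1, h2 = h2, margin = margin,
                 samples = as.integer(samples), seed = seed),
            class = "spray_scene_config")
}

#' Generate a random feasible spray scene
#'
#' Draws a weed-pair distance and cylinder parameters from the configured
#' ranges, resampling (bounded retries) until the scene is feasible: apex
#' height above plant height plus margin and the cylinder footprint strictly
#' between the two weeds.
#'
#' @param cfg a \code{\link{spray_scene_config}}.
#' @return a \code{\link{spray_scene}} with S at the origin and E on the x
#'   axis.
#' @export
gen_spray_scene <- function(cfg = spray_scene_config()) {
  stopifnot(inherits(cfg, "spray_scene_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  for (try in 1:100) {
    L <- stats::runif(1, cfg$dist_range[1], cfg$dist_range[2])
    w1 <- stats::runif(1, cfg$w1_range[1], cfg$w1_range[2])
    w2 <- stats::runif(1, cfg$w2_range[1], cfg$w2_range[2])
    h3 <- stats::runif(1, cfg$h3_range[1], cfg$h3_range[2])
    if (cfg$h1 + cfg$h2 > h3 + cfg$margin && w1 + 2 * w2 < L) {
      return(spray_scene(s = c(0, 0, 0), e = c(L, 0, 0),
                         obstacle = crop_obstacle(w1, w2, h3),
                         params = trajectory_params(cfg$h1, cfg$h2, cfg$margin,
                                                    cfg$samples)))
    }
  }
  stop("no feasible scene drawn after 100 retries; ranges are inconsistent",
       call. = FALSE)
}

#' The reference simulation spray scene
#'
#' Crop cylinder of height 150 mm centred 100 mm from the start point
#' (standoff w1 = 60 mm, radius w2 = 40 mm), planning apex at 170 mm
#' (h1 = 20, h2 = 150), weed pair 200 mm apart so the scene is symmetric.
#'
#' @param margin clearance margin (mm).
#' @param samples polyline samples per phase.
#' @return a \code{\link{spray_scene}}.
#' @export
reference_spray_scene <- function(margin = 0, samples = 200) {
  spray_scene(s = c(0, 0, 0), e = c(200, 0, 0),
              obstacle = crop_obstacle(w1 = 60, w2 = 40, h3 = 150),
              params = trajectory_params(h1 = 20, h2 = 150, margin = margin,
                                         samples = samples))
}

#' Construct detection tables with prescribed match counts
#'
#' Builds ground-truth and prediction box sets whose greedy matching at
#' IoU 0.5 yields exactly the requested TP/FP/FN tallies: matched predictions
#' are small jitters of their ground-truth boxes, false positives sit on
#' empty grid cells, and \code{fn} ground-truth boxes get no prediction.
#'
#' @param tp,fp,fn requested counts (non-negative integers).
#' @param box_size box side length (pixels).
#' @param seed RNG seed for jitter and confidences.
#' @return list with \code{preds} (data.frame incl. conf) and \code{gts}.
#' @export
gen_detection_tables <- function(tp, fp, fn, box_size = 40, seed = NULL) {
  v <- c(tp, fp, fn)
  if (any(v < 0) || any(v != round(v)))
    stop("tp, fp, fn must be non-negative integers", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_gt <- tp + fn
  n_cells <- n_gt + fp
  pitch <- box_size * 3
  ncol_grid <- max(1, ceiling(sqrt(n_cells)))
  cell_xy <- function(k) c((k - 1) %% ncol_grid, (k - 1) %/% ncol_grid) * pitch
  mk_box <- function(origin) c(origin[1], origin[2],
                               origin[1] + box_size, origin[2] + box_size)
  gts <- if (n_gt) do.call(rbind, lapply(seq_len(n_gt), function(k) {
    b <- mk_box(cell_xy(k))
    data.frame(xmin = b[1], ymin = b[2], xmax = b[3], ymax = b[4])
  })) else data.frame(xmin = numeric(), ymin = numeric(),
                      xmax = numeric(), ymax = numeric())
  preds <- list()
  if (tp) preds <- c(preds, lapply(seq_len(tp), function(k) {
    jit <- stats::runif(2, -box_size * 0.05, box_size * 0.05)
    b <- mk_box(cell_xy(k) + jit)
    data.frame(xmin = b[1], ymin = b[2], xmax = b[3], ymax = b[4],
               conf = stats::runif(1, 0.75, 0.99))
  }))
  if (fp) preds <- c(preds, lapply(seq_len(fp), function(k) {
    b <- mk_box(cell_xy(n_gt + k))
    data.frame(xmin = b[1], ymin = b[2], xmax = b[3], ymax = b[4],
               conf = stats::runif(1, 0.3, 0.7))
  }))
  preds <- if (length(preds)) do.call(rbind, preds) else
    data.frame(xmin = numeric(), ymin = numeric(), xmax = numeric(),
               ymax = numeric(), conf = numeric())
  list(preds = preds, gts = gts)
}

#' Dataset size after augmentation
#'
#' Each source image contributes itself plus \code{n_augmentations} altered
#' copies (brightness changes, mirroring, ...).
#'
#' @param n_images number of curated source images.
#' @param n_augmentations augmented copies per image.
#' @return total image count.
#' @export
augmented_dataset_size <- function(n_images, n_augmentations = 3) {
  stopifnot(n_images >= 0, n_augmentations >= 0)
  n_images * (1 + n_augmentations)
}

#' Segmentation recall against generator ground truth
#'
#' Runs the full segmentation chain on a synthetic field scene and scores a
#' ground-truth weed as recovered when some reported centroid lies within
#' \code{tol_px} of its true centroid (each report may claim one truth weed).
#'
#' @param scene a \code{\link{gen_field_image}} result.
#' @param cfg a \code{\link{seg_config}}.
#' @param tol_px centroid matching tolerance (pixels).
#' @return list with \code{recall} (fraction in [0, 1]), \code{n_truth},
#'   \code{n_recovered}, \code{n_reported} and the segmentation result.
#' @export
segmentation_recall <- function(scene, cfg = seg_config(), tol_px = 3) {
  stopifnot(inherits(scene, "field_scene"))
  seg <- segment_weeds(scene$image, scene$crop_boxes, cfg)
  truth <- scene$weeds
  n_truth <- nrow(truth)
  if (n_truth == 0L)
    return(list(recall = NA_real_, n_truth = 0L, n_recovered = 0L,
                n_reported = nrow(seg$weeds), segmentation = seg))
  rep_xy <- as.matrix(seg$weeds[, c("centroid_x", "centroid_y")])
  used <- rep(FALSE, nrow(seg$weeds))
  recovered <- 0L
  for (i in seq_len(n_truth)) {
    if (!nrow(rep_xy)) break
    d <- sqrt((rep_xy[, 1] - truth$centroid_x[i])^2 +
                (rep_xy[, 2] - truth$centroid_y[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_px) {
      used[j] <- TRUE
      recovered <- recovered + 1L
    }
  }
  list(recall = recovered / n_truth, n_truth = n_truth,
       n_recovered = recovered, n_reported = nrow(seg$weeds),
       segmentation = seg)
}
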