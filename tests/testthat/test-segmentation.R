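make_rgb <- function(r, g, b) {
  h <- nrow(r)
  array(c(r, g, b), dim = c(h, ncol(r), 3))
}

test_that("excess-green map follows 2G - R - B", {
  img <- array(0, dim = c(2, 2, 3))
  img[1, 1, ] <- c(0, 255, 0)     # pure green
  img[1, 2, ] <- c(130, 130, 130) # gray
  img[2, 1, ] <- c(255, 0, 0)     # pure red
  img[2, 2, ] <- c(10, 80, 30)
  m <- exg_map(img)
  expect_equal(m[1, 1], 510)
  expect_equal(m[1, 2], 0)
  expect_equal(m[2, 1], -255)
  expect_equal(m[2, 2], 2 * 80 - 10 - 30)
})

test_that("Otsu binarization splits a bimodal map and matches the exhaustive oracle", {
  set.seed(5)
  map <- matrix(c(rep(40, 50), rep(200, 50)), 10, 10)
  mask <- otsu_binarize(map)
  thr <- attr(mask, "threshold")
  expect_gt(thr, 255 * (40 - 40) / 160)      # threshold strictly between modes
  expect_lt(thr, 255)
  expect_equal(unname(mask[map == 200]), rep(1L, 50))
  expect_equal(unname(mask[map == 40]), rep(0L, 50))

  # exhaustive between-class-variance argmax on the normalized map: the
  # resulting foreground set must agree with the brute-force oracle's
  for (i in 1:5) {
    map <- matrix(sample(c(stats::rnorm(60, 60, 10), stats::rnorm(40, 190, 10))),
                  10, 10)
    mask <- otsu_binarize(map)
    rng <- range(map)
    norm <- (map - rng[1]) / diff(rng) * 255
    t_oracle <- otsu_bruteforce(norm)
    expect_identical(which(mask == 1L), which(norm > t_oracle))
  }

  # inverting the map swaps foreground/background sizes
  map <- matrix(c(rep(40, 30), rep(200, 70)), 10, 10)
  m1 <- otsu_binarize(map)
  m2 <- otsu_binarize(-map)
  expect_equal(sum(m1 == 1), sum(m2 == 0))
  expect_equal(sum(m1 == 0), sum(m2 == 1))

  expect_warning(empty <- otsu_binarize(matrix(7, 5, 5)), "constant")
  expect_equal(sum(empty), 0)
})

test_that("morphological opening removes specks and preserves large blobs", {
  speck <- matrix(0L, 20, 20); speck[10, 10] <- 1L
  expect_equal(sum(morph_refine(speck)), 0)

  square <- rect_mask(80, 80, list(c(16, 16, 50, 50)))
  opened <- morph_refine(square)
  expect_lt(abs(sum(opened) - 2500) / 2500, 0.05)

  empty <- matrix(0L, 15, 15)
  expect_equal(morph_refine(empty), empty)
})

test_that("connected-domain filtering retains areas >= mcds with 8-connectivity", {
  mask <- rect_mask(60, 60, list(c(5, 5, 5, 6),     # 30 px
                                 c(20, 20, 5, 10),  # 50 px
                                 c(40, 30, 8, 10))) # 80 px
  cs <- filter_components(mask, mcds = 50)
  expect_equal(nrow(cs$stats), 2)
  expect_setequal(cs$stats$area, c(50, 80))

  cs1 <- filter_components(mask, mcds = 1)
  expect_equal(nrow(cs1$stats), 3)
  expect_equal(sum(cs1$stats$area), sum(mask))

  # monotone filter: components kept at mcds 50 are kept at mcds 30
  cs30 <- filter_components(mask, mcds = 30)
  key <- function(s) paste(s$xmin, s$ymin, s$xmax, s$ymax)
  expect_true(all(key(cs$stats) %in% key(cs30$stats)))

  # diagonal adjacency merges under 8-connectivity, splits under 4
  diag_mask <- matrix(0L, 6, 6)
  diag_mask[2, 2] <- 1L; diag_mask[3, 3] <- 1L
  expect_equal(nrow(filter_components(diag_mask, mcds = 1)$stats), 1)
  expect_equal(nrow(filter_components(diag_mask, mcds = 1,
                                      connectivity = 4)$stats), 2)
})

test_that("weed extraction reports exact centroids and outer rectangles", {
  sq <- rect_mask(40, 40, list(c(10, 15, 11, 11)))  # rows 10..20, cols 15..25
  w <- extract_weeds(filter_components(sq, 10))
  expect_equal(w$centroid_y, 14)   # 0-based centre of rows 10..20 -> 15th row
  expect_equal(w$centroid_x, 19)
  expect_equal(c(w$xmin, w$ymin, w$xmax, w$ymax), c(14, 9, 25, 20))

  two <- rect_mask(40, 40, list(c(25, 3, 6, 6), c(4, 28, 5, 8)))
  ww <- extract_weeds(filter_components(two, 10))
  expect_equal(nrow(ww), 2)
  expect_true(ww$ymin[1] < ww$ymin[2])  # stable top-left ordering

  # L-shaped blob: centroid equals the brute-force pixel mean
  L <- matrix(0L, 30, 30)
  L[10:20, 10:12] <- 1L
  L[18:20, 10:20] <- 1L
  wl <- extract_weeds(filter_components(L, 10))
  px <- which(L == 1L, arr.ind = TRUE)
  expect_equal(wl$centroid_x, mean(px[, 2] - 1))
  expect_equal(wl$centroid_y, mean(px[, 1] - 1))

  # rotated mode covers a tilted blob more tightly than its axis-aligned box
  tilt <- matrix(0L, 60, 60)
  for (k in 0:25) tilt[20 + k, (14 + k):(18 + k)] <- 1L
  wr <- extract_weeds(filter_components(tilt, 10), rect_mode = "rotated")
  aa_area <- (wr$xmax - wr$xmin) * (wr$ymax - wr$ymin)
  expect_lt(wr$rect_w * wr$rect_h, aa_area)
})

test_that("crop masking blanks boxes and keeps outside weed pixels", {
  img <- array(90, dim = c(30, 30, 3))
  allbox <- data.frame(xmin = 0, ymin = 0, xmax = 30, ymax = 30)
  expect_equal(sum(mask_crops(img, allbox)), 0)
  expect_identical(mask_crops(img, NULL), img)
  expect_identical(mask_crops(img, allbox[0, ]), img)

  # weed blob half under a crop box: only the outside part survives
  r <- matrix(60, 40, 40); g <- matrix(60, 40, 40); b <- matrix(60, 40, 40)
  g[11:20, 6:25] <- 220; r[11:20, 6:25] <- 50; b[11:20, 6:25] <- 50
  img2 <- make_rgb(r, g, b)
  box <- data.frame(xmin = 5, ymin = 0, xmax = 16, ymax = 40)
  seg <- segment_weeds(img2, box, seg_config(mcds = 10))
  expect_equal(nrow(seg$weeds), 1)
  expect_gte(seg$weeds$xmin, 16)
  # and the crop-exclusion invariant: no weed rectangle enters the box
  expect_true(all(seg$weeds$xmin >= box$xmax | seg$weeds$xmax <= box$xmin |
                    seg$weeds$ymin >= box$ymax | seg$weeds$ymax <= box$ymin))
})

test_that("pixel-robot calibration is an invertible affine map", {
  cal1 <- camera_calib(mm_per_px = 1)
  expect_equal(unname(pixel_to_robot(c(12, 34), cal1)[1, ]), c(12, 34, 0))

  cal <- camera_calib(mm_per_px = 0.5, camera_origin_mm = c(0, 0),
                      advance_offset_mm = 100)
  expect_equal(unname(pixel_to_robot(c(200, 0), cal)[1, ]), c(200, 0, 0))

  set.seed(2)
  px <- matrix(stats::runif(40, 0, 1200), ncol = 2)
  back <- robot_to_pixel(pixel_to_robot(px, cal), cal)
  expect_lt(max(abs(back - px)), 1e-9)
  expect_error(pixel_to_robot(c(1, 2), list(mm_per_px = 1)), "camera_calib")
})

test_that("the full segmentation chain is deterministic and recovers drawn weeds", {
  scene <- gen_field_image(field_scene_config(width = 320, height = 320,
                                              n_weeds = 8, n_crops = 1,
                                              seed = 77))
  s1 <- segment_weeds(scene$image, scene$crop_boxes)
  s2 <- segment_weeds(scene$image, scene$crop_boxes)
  expect_identical(s1$weeds, s2$weeds)

  res <- segmentation_recall(scene, seg_config(mcds = 50), tol_px = 3)
  expect_gte(res$recall, 0.95)
  expect_true(all(res$segmentation$weeds$area >= 50))
})

test_that("blobs below the minimum connected domain size are never reported", {
  tiny <- gen_field_image(field_scene_config(width = 320, height = 320,
                                             n_weeds = 10, n_crops = 0,
                                             weed_area_px = c(15, 35),
                                             seed = 31))
  seg <- segment_weeds(tiny$image, NULL, seg_config(mcds = 50))
  expect_equal(nrow(seg$weeds), 0)
})
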