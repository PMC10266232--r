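test_that("cubic Bezier evaluation interpolates endpoints and the hand-expanded midpoint", {
  seg <- bezier_segment(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  expect_identical(eval_cubic_bezier(seg, 0)[1, ], c(u = 0, z = 0))
  expect_identical(eval_cubic_bezier(seg, 1)[1, ], c(u = 1, z = 0))
  # weights at t = 0.5 are 1/8, 3/8, 3/8, 1/8
  expect_equal(eval_cubic_bezier(seg, 0.5)[1, ], c(u = 0.5, z = 0.75))
  expect_error(eval_cubic_bezier(seg, 1.2), "\\[0, 1\\]")
  expect_error(eval_cubic_bezier(seg, -0.1), "\\[0, 1\\]")

  set.seed(41)
  for (i in 1:25) {
    s <- random_segment()
    P <- unclass(s)
    expect_identical(eval_cubic_bezier(s, 0)[1, ], c(u = P[1, 1], z = P[1, 2]))
    expect_identical(eval_cubic_bezier(s, 1)[1, ], c(u = P[4, 1], z = P[4, 2]))
  }
})

test_that("sampled Bezier points stay inside the control-point convex hull", {
  set.seed(42)
  for (i in 1:20) {
    s <- random_segment()
    pts <- eval_cubic_bezier(s, seq(0, 1, length.out = 101))
    expect_true(all(in_hull(pts, unclass(s), tol = 1e-9)))
  }
})

test_that("Bezier curvature matches a finite-difference oracle and known special cases", {
  # collinear control points: a straight segment has zero curvature
  line <- bezier_segment(c(0, 0), c(1, 1), c(2, 2), c(3, 3))
  expect_equal(bezier_curvature(line, seq(0.05, 0.95, by = 0.1)),
               rep(0, 10), tolerance = 1e-12)

  seg <- bezier_segment(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  for (t in c(0.2, 0.5, 0.8)) {
    k_fd <- fd_curvature(function(tt) eval_cubic_bezier(seg, tt)[1, ], t)
    expect_equal(bezier_curvature(seg, t), k_fd, tolerance = 1e-6)
  }

  # quarter-circle approximation (c = 0.5523): midpoint curvature is
  # 18 c (0.5 - 0.25 c) / (3 (0.5 - 0.25 c) sqrt(2))^3 / R = 0.99368/R,
  # i.e. within 1% of the true circle curvature
  R <- 100; cc <- 0.5523
  qc <- bezier_segment(c(R, 0), c(R, cc * R), c(cc * R, R), c(0, R))
  expect_equal(bezier_curvature(qc, 0.5), 1 / R, tolerance = 0.01)
  k_exact <- 18 * cc * (0.5 - 0.25 * cc) / (3 * (0.5 - 0.25 * cc) * sqrt(2))^3 / R
  expect_equal(bezier_curvature(qc, 0.5), k_exact, tolerance = 1e-9)

  degen <- bezier_segment(c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  expect_error(bezier_curvature(degen, 0.5), "degenerate")
})

test_that("build_arch places phases per the control-offset construction", {
  obs <- crop_obstacle(w1 = 60, w2 = 40, h3 = 150)
  par <- trajectory_params(h1 = 20, h2 = 150, samples = 120)

  # degenerate control polygon still interpolates P0 -> P3
  traj0 <- build_arch(c(0, 0), c(200, 0), obs, par, alpha = 0, beta = 0)
  expect_equal(unname(unclass(traj0$bezier_up)[1, ]), traj0$p0)
  expect_equal(unname(unclass(traj0$bezier_up)[2, ]), traj0$p0)  # P1 = P0
  expect_equal(unname(unclass(traj0$bezier_up)[3, ]), traj0$p3)  # P2 = P3
  bez_pts <- eval_cubic_bezier(traj0$bezier_up, c(0, 1))
  expect_equal(unname(bez_pts[1, ]), traj0$p0)
  expect_equal(unname(bez_pts[2, ]), traj0$p3)

  # reference scene: apex height is h1 + h2 = 170 mm
  expect_equal(max(traj0$polyline[, 2]), 170)
  # the horizontal phase holds the apex height over the whole footprint
  horiz <- traj0$polyline[traj0$phase == "horizontal", ]
  expect_true(all(abs(horiz[, 2] - 170) < 1e-12))
  expect_equal(range(horiz[, 1]), c(60, 140))
  # polyline starts at s, ends at e, and phases are continuous by sampling
  expect_equal(unname(traj0$polyline[1, ]), c(0, 0))
  expect_equal(unname(traj0$polyline[nrow(traj0$polyline), ]), c(200, 0))
  expect_true(all(sqrt(rowSums(diff(traj0$polyline)^2)) < 5))

  # control offsets move P1 up and P2 back towards S
  traj <- build_arch(c(0, 0), c(200, 0), obs, par, alpha = 30, beta = 25)
  expect_equal(unname(unclass(traj$bezier_up)[2, ]), c(0, 50))
  expect_equal(unname(unclass(traj$bezier_up)[3, ]), c(35, 170))

  # offsets outside the curvature-constraint bounds are rejected
  expect_error(build_arch(c(0, 0), c(200, 0), obs, par, alpha = 0.8 * 150 + 1),
               "alpha")
  expect_error(build_arch(c(0, 0), c(200, 0), obs, par, beta = 0.8 * 100 + 1),
               "beta")
  # apex at or below the plant is an infeasible scene
  tall <- crop_obstacle(60, 40, 180)
  expect_error(build_arch(c(0, 0), c(200, 0), tall, par), "infeasible")
})

test_that("a symmetric scene yields a mirror-symmetric polyline", {
  obs <- crop_obstacle(w1 = 60, w2 = 40, h3 = 150)
  par <- trajectory_params(h1 = 20, h2 = 150, samples = 150)
  traj <- build_arch(c(0, 0), c(200, 0), obs, par, alpha = 40, beta = 30)
  mirrored <- cbind(200 - traj$polyline[, 1], traj$polyline[, 2])
  mirrored <- mirrored[nrow(mirrored):1, ]
  expect_equal(unname(traj$polyline), unname(mirrored), tolerance = 1e-9)
})

test_that("path length dominates the straight span and converges under refinement", {
  obs <- crop_obstacle(60, 40, 150)
  for (ab in list(c(0, 0), c(50, 40), c(120, 80))) {
    traj <- build_arch(c(0, 0), c(200, 0), obs, trajectory_params(20, 150),
                       alpha = ab[1], beta = ab[2])
    expect_gte(path_length(traj), 200)
  }
  l1 <- path_length(build_arch(c(0, 0), c(200, 0), obs,
                               trajectory_params(20, 150, samples = 200),
                               alpha = 60, beta = 50))
  l2 <- path_length(build_arch(c(0, 0), c(200, 0), obs,
                               trajectory_params(20, 150, samples = 400),
                               alpha = 60, beta = 50))
  expect_lt(abs(l2 - l1) / l1, 0.001)
})

test_that("clearance checking flags sagging, boundaries and out-of-span footprints", {
  obs <- crop_obstacle(60, 40, 150)
  par <- trajectory_params(20, 150)
  traj <- build_arch(c(0, 0), c(200, 0), obs, par, alpha = 20, beta = 30)
  rep0 <- check_clearance(traj, obs, margin = 0)
  expect_true(rep0$feasible)
  expect_equal(rep0$min_margin, 20, tolerance = 1e-9)

  # raising the plant above the apex makes the same path infeasible
  expect_false(check_clearance(traj, crop_obstacle(60, 40, 171))$feasible)

  # boundary bisection on the achieved margin
  m <- rep0$min_margin
  expect_true(check_clearance(traj, obs, margin = m)$feasible)
  expect_false(check_clearance(traj, obs, margin = m + 1e-9)$feasible)

  # footprint beyond the trajectory span: warning, trivially feasible
  far <- crop_obstacle(w1 = 500, w2 = 10, h3 = 150)
  expect_warning(rep_far <- check_clearance(traj, far), "outside")
  expect_true(rep_far$feasible)
  expect_false(rep_far$footprint_crossed)
})

test_that("raising alpha never lowers the clearance margin in the reference scene", {
  obs <- crop_obstacle(60, 40, 150)
  par <- trajectory_params(20, 150, samples = 100)
  for (beta in c(0, 40, 80)) {
    margins <- vapply(seq(0, 120, length.out = 7), function(a) {
      check_clearance(build_arch(c(0, 0), c(200, 0), obs, par,
                                 alpha = a, beta = beta))$min_margin
    }, numeric(1))
    expect_true(all(diff(margins) >= -1e-9))
  }
})

test_that("plane embedding is a rigid, invertible map taking E onto the u axis", {
  emb <- plane_embedding(c(0, 0, 0), c(300, 0, 0))
  expect_equal(unname(emb$to_plane(c(300, 0, 0))[1, ]), c(300, 0))

  emb90 <- plane_embedding(c(0, 0, 0), c(0, 300, 0))
  expect_equal(unname(emb90$to_plane(c(0, 300, 0))[1, ]), c(300, 0))
  p <- c(0, 120, 55)
  expect_lt(max(abs(emb90$to_world(emb90$to_plane(p)) - p)), 1e-9)

  set.seed(99)
  for (i in 1:100) {
    s3 <- c(stats::runif(2, -500, 500), 0)
    e3 <- c(stats::runif(2, -500, 500), 0)
    if (sqrt(sum((e3 - s3)^2)) < 1e-6) next
    emb <- plane_embedding(s3, e3)
    expect_lt(abs(emb$to_plane(e3)[1, 1] - sqrt(sum((e3 - s3)^2))), 1e-9)
    q <- emb$to_plane(e3)
    expect_lt(max(abs(emb$to_world(q) - e3)), 1e-9)
  }
  expect_error(plane_embedding(c(1, 2, 0), c(1, 2, 0)), "degenerate")
})

test_that("path length is invariant under the plane embedding", {
  sc <- reference_spray_scene()
  emb <- plane_embedding(c(50, -80, 0), c(150, 120, 0))
  traj <- build_arch(c(0, 0), c(emb$span, 0), sc$obstacle, sc$params,
                     alpha = 30, beta = 20, embedding = emb)
  expect_equal(path_length(trajectory_world(traj)), path_length(traj),
               tolerance = 1e-9)
})

test_that("scene JSON and trajectory CSV round-trip through files", {
  sc <- reference_spray_scene()
  f <- tempfile(fileext = ".json")
  write_scene(sc, f)
  sc2 <- read_scene(f)
  expect_equal(sc2$obstacle$w1, 60)
  expect_equal(sc2$params$h1 + sc2$params$h2, 170)
  expect_equal(sc2$e, c(200, 0, 0))

  emb <- plane_embedding(sc$s, sc$e)
  traj <- build_arch(c(0, 0), c(emb$span, 0), sc$obstacle, sc$params,
                     embedding = emb)
  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, csv)
  df <- read.csv(csv)
  expect_named(df, c("phase", "t", "u_mm", "z_mm", "x_mm", "y_mm"))
  expect_equal(df$x_mm, df$u_mm, tolerance = 1e-9)  # embedding along x
  expect_equal(max(df$z_mm), 170)
})
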