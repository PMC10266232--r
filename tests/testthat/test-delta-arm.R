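test_that("points on the central axis give three equal joint angles", {
  g <- delta_geometry()
  for (z in c(-380, -450, -520)) {
    a <- inverse_kinematics(c(0, 0, z), g)
    expect_equal(a[1], a[2], tolerance = 1e-12)
    expect_equal(a[2], a[3], tolerance = 1e-12)
  }
  # and symmetric angles place the effector back on the axis
  p <- forward_kinematics(inverse_kinematics(c(0, 0, -450), g), g)
  expect_lt(max(abs(p[1:2])), 1e-9)
})

test_that("inverse and forward kinematics round-trip across the workspace", {
  g <- delta_geometry()
  set.seed(17)
  n_ok <- 0
  for (i in 1:250) {
    pt <- c(stats::runif(1, -150, 150), stats::runif(1, -150, 150),
            stats::runif(1, -560, -360))
    ang <- tryCatch(inverse_kinematics(pt, g), error = function(e) NULL)
    if (is.null(ang)) next
    n_ok <- n_ok + 1
    expect_lt(max(abs(forward_kinematics(ang, g) - pt)), 1e-6)
  }
  expect_gt(n_ok, 200)  # the sampled box is largely inside the workspace

  # IK(FK(angles)) identity on valid triples
  for (i in 1:25) {
    ang <- stats::runif(3, 0.3, 1.2)
    p <- forward_kinematics(ang, g)
    expect_lt(max(abs(inverse_kinematics(p, g) - ang)), 1e-6)
  }
})

test_that("descending the central axis raises all three angles monotonically", {
  g <- delta_geometry()
  zs <- seq(-360, -560, length.out = 15)
  th <- t(vapply(zs, function(z) inverse_kinematics(c(0, 0, z), g), numeric(3)))
  expect_true(all(diff(th[, 1]) > 0))
  expect_true(all(diff(th[, 2]) > 0))
  expect_true(all(diff(th[, 3]) > 0))
})

test_that("unreachable targets raise a workspace error naming the arm", {
  g <- delta_geometry()
  expect_error(inverse_kinematics(c(2000, 0, -450), g), "arm")
})

test_that("discretization yields equal arc-length spacing with exact endpoints", {
  # straight 100 mm segment, 5 points -> 25 mm spacing
  seg <- cbind(seq(0, 100, length.out = 11), 0, 0)
  d5 <- discretize_trajectory(seg, 5)
  expect_equal(diff(d5[, 1]), rep(25, 4))

  d2 <- discretize_trajectory(seg, 2)
  expect_equal(unname(d2), unname(seg[c(1, 11), ]))
  expect_error(discretize_trajectory(seg, 1), ">= 2")

  # on the arch: spacing measured along the polyline is uniform
  sc <- reference_spray_scene()
  emb <- plane_embedding(sc$s, sc$e)
  traj <- build_arch(c(0, 0), c(emb$span, 0), sc$obstacle, sc$params,
                     alpha = 30, beta = 25, embedding = emb)
  pts <- discretize_trajectory(traj, 100)
  expect_equal(unname(pts[1, ]), c(0, 0, 0))
  expect_equal(unname(pts[100, ]), c(200, 0, 0))
  # arc position of each sample, found by projecting onto the polyline
  poly <- trajectory_world(traj)
  seglen <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seglen))
  arc_at <- vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    best <- Inf; arc <- NA_real_
    for (j in seq_len(nrow(poly) - 1)) {
      if (seglen[j] < 1e-12) next
      a <- poly[j, ]; b <- poly[j + 1, ]
      tt <- sum((p - a) * (b - a)) / sum((b - a)^2)
      tt <- min(max(tt, 0), 1)
      d <- sum((a + tt * (b - a) - p)^2)
      if (d < best) { best <- d; arc <- cum[j] + tt * seglen[j] }
    }
    arc
  }, numeric(1))
  spac <- diff(arc_at)
  expect_lt(max(abs(spac - mean(spac))) / mean(spac), 1e-6)
})

test_that("joint deltas telescope, vanish on constant input and flip under reversal", {
  g <- delta_geometry()
  const <- matrix(rep(c(20, -15, 30), each = 6), 6, 3)
  jd <- joint_deltas(const, g)
  expect_equal(max(abs(jd$deltas)), 0)

  sc <- reference_spray_scene()
  emb <- plane_embedding(sc$s, sc$e)
  traj <- build_arch(c(0, 0), c(emb$span, 0), sc$obstacle, sc$params,
                     alpha = 20, beta = 20, embedding = emb)
  pts <- discretize_trajectory(traj, 100)
  jd <- joint_deltas(pts, g)
  expect_lt(max(abs(colSums(jd$deltas) -
                      (jd$angles[100, ] - jd$angles[1, ]))), 1e-9)
  # branch consistency: no elbow flips along the continuous trajectory
  expect_lt(max(abs(jd$deltas)) * 180 / pi, 10)

  rev_jd <- joint_deltas(pts[100:1, ], g)
  expect_equal(unname(rev_jd$deltas), unname(-jd$deltas[99:1, ]),
               tolerance = 1e-12)

  bad <- rbind(c(0, 0, 0), c(5000, 0, 0))
  expect_error(joint_deltas(bad, g), "point 2")
})

test_that("joint command CSV lists positions, angles and increments", {
  g <- delta_geometry()
  pts <- cbind(seq(0, 50, length.out = 5), 0, seq(0, 100, length.out = 5))
  jd <- joint_deltas(pts, g)
  f <- tempfile(fileext = ".csv")
  write_joint_csv(pts, jd, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 5)
  expect_named(df, c("step", "x", "y", "z", "theta1", "theta2", "theta3",
                     "dtheta1", "dtheta2", "dtheta3"))
  expect_equal(df$dtheta1[1], 0)
  expect_equal(cumsum(df$dtheta2)[5] + df$theta2[1], df$theta2[5],
               tolerance = 1e-9)
})
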